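flat_binary_volume <- function(depth_idx = 50L, nz = 100L, n = 20L, h = 21) {
  a <- array(0, dim = c(n, nz, n))
  a[, depth_idx:nz, ] <- 200
  volume3d(a, spacing = c(h, h, h))
}

test_that("tilt estimation is exact for a horizontal interface", {
  expect_lt(abs(estimate_tilt(flat_binary_volume())), 1e-9)
})

test_that("a 2-degree synthetic tilt is recovered within 0.1 degree", {
  p <- clean_params(tilt_deg = 2, plane_slope_deg = 0,
                    waviness_amplitude = 0, roughness_amplitude = 10,
                    seed = 41)
  ct <- simulate_ct_volume(generate_ground_truth(p))
  est <- estimate_tilt(ct)
  expect_lt(abs(est - 2), 0.1)
  # fixed point: derotating and re-estimating gives ~0
  expect_lt(abs(estimate_tilt(rotate_volume(ct, -est))), 0.1)
})

test_that("rotation is identity at zero angle and inverts within resampling error", {
  p <- clean_params(seed = 42)
  ct <- simulate_ct_volume(generate_ground_truth(p))
  expect_identical(rotate_volume(ct, 0)$intensities, ct$intensities)
  rt <- rotate_volume(rotate_volume(ct, 3), -3)
  dr <- diff(range(ct$intensities))
  interior <- rt$intensities[, 10:(n_depth(ct) - 10), 10:(n_lateral(ct) - 10)]
  orig <- ct$intensities[, 10:(n_depth(ct) - 10), 10:(n_lateral(ct) - 10)]
  expect_lt(mean(abs(interior - orig)) / dr, 0.02)
  cv <- volume3d(array(7, dim = c(2, 30, 30)), spacing = c(21, 21, 21))
  expect_equal(rotate_volume(cv, 5)$intensities, cv$intensities)
  expect_error(rotate_volume(ct, 20), "15")
})

test_that("Otsu separates a two-point histogram and rejects constants", {
  x <- array(c(rep(0, 50), rep(255, 50)), dim = c(1, 10, 10))
  vol <- volume3d(x, spacing = c(1, 1, 1))
  thr <- otsu_threshold(vol)
  expect_equal(sum(binarize(vol, thr)$mask), 50)
  expect_error(otsu_threshold(volume3d(array(3, dim = c(1, 5, 5)),
                                       spacing = c(1, 1, 1))), "constant")
})

test_that("Otsu equals the exhaustive between-class-variance maximizer", {
  set.seed(101)
  for (r in 1:5) {
    x <- c(rnorm(400, 30, 6), rnorm(600, 80, 12))
    expect_equal(otsu_threshold(x), otsu_brute(x))
  }
})

test_that("Otsu commutes with positive affine intensity maps at matched binning", {
  set.seed(102)
  x <- c(rnorm(300, 10, 2), rnorm(300, 30, 4))
  t1 <- otsu_threshold(x)
  t2 <- otsu_threshold(3.5 * x + 11)
  expect_equal(t2, 3.5 * t1 + 11, tolerance = 1e-9)
})

test_that("binarization counts are monotone in the threshold", {
  set.seed(103)
  vol <- volume3d(array(runif(4000, 0, 100), dim = c(4, 20, 50)),
                  spacing = c(1, 1, 1))
  counts <- vapply(c(10, 30, 50, 70), function(t) sum(binarize(vol, t)$mask),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("first abrupt change finds a flat interface exactly", {
  bv <- binarize(flat_binary_volume(depth_idx = 51L), 100)
  s <- extract_surface_3d_ct(bv)
  expect_true(all(s$heights == 50 * 21))
  expect_true(all(s$valid))
})

test_that("hole columns are filled by linear interpolation between neighbours", {
  a <- array(0, dim = c(1, 100, 5))
  depth <- c(51, 51, NA, 53, 53)       # column 3 is a hole
  for (j in c(1, 2, 4, 5)) a[1, depth[j]:100, j] <- 200
  s <- extract_surface_3d_ct(binarize(volume3d(a, spacing = c(21, 21, 21)), 100))
  expect_equal(s$heights[1, 3], (50 * 21 + 52 * 21) / 2)   # 1050 & 1092 -> 1071
  expect_false(s$valid[1, 3])
  expect_error(extract_surface_3d_ct(
    binarize(volume3d(array(0, dim = c(1, 10, 5)), spacing = c(21, 21, 21)), 100)),
    "no interface")
})

test_that("a stepped interface is reproduced exactly", {
  a <- array(0, dim = c(2, 100, 10))
  a[, 41:100, 1:5] <- 200
  a[, 61:100, 6:10] <- 200
  s <- extract_surface_3d_ct(binarize(volume3d(a, spacing = c(21, 21, 21)), 100),
                             window_um = 500)
  expect_true(all(s$heights[, 1:5] == 40 * 21))
  expect_true(all(s$heights[, 6:10] == 60 * 21))
})

test_that("noise-free CT recovery error stays within one voxel off holes", {
  p <- clean_params(hole_fraction = 0.04, seed = 44)
  gt <- generate_ground_truth(p)
  ct <- simulate_ct_volume(gt)
  s <- extract_surface_3d_ct(binarize(ct, otsu_threshold(ct)))
  truth <- attr(ct, "ct_surface")
  ok <- !dilate1(gt$hole_mask)
  expect_lt(max(abs(s$heights - truth$heights)[ok]), p$ct_spacing + 1e-9)
  expect_true(all(is.finite(s$heights)))
})
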