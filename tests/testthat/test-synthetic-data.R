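test_that("degenerate amplitudes give an exactly planar surface", {
  p <- clean_params(waviness_amplitude = 0, roughness_amplitude = 0,
                    plane_slope_deg = 0, seed = 2)
  s <- generate_ground_truth_surface(p)
  expect_equal(max(s$heights) - min(s$heights), 0)
  expect_equal(s$heights[1, 1], p$surface_depth_um)
  comp <- attr(s, "components")
  expect_equal(max(abs(comp$waviness)), 0)
  expect_equal(max(abs(comp$roughness)), 0)
})

test_that("zero roughness leaves near-zero SRa after order-5 detrending", {
  p <- clean_params(roughness_amplitude = 0, waviness_amplitude = 120, seed = 3)
  s <- generate_ground_truth_surface(p)
  pan <- smoothness_panel(s)
  expect_gt(pan$SWa, 10)
  expect_lt(pan$SRa, 0.02 * pan$SWa)   # only poly-5 truncation residue remains
})

test_that("the seed fully determines surfaces, masks and volumes", {
  p <- quick_params(seed = 9)
  gt1 <- generate_ground_truth(p)
  gt2 <- generate_ground_truth(p)
  expect_identical(gt1$surface_fun, gt2$surface_fun)
  expect_identical(gt1$crack_mask, gt2$crack_mask)
  expect_identical(gt1$true_transform, gt2$true_transform)
  expect_identical(simulate_us_volume(gt1)$volume$intensities,
                   simulate_us_volume(gt2)$volume$intensities)
  expect_identical(simulate_ct_volume(gt1)$intensities,
                   simulate_ct_volume(gt2)$intensities)
})

test_that("masks stay sparse and the surface stays inside the depth range", {
  p <- quick_params(seed = 21)
  gt <- generate_ground_truth(p)
  expect_lt(mean(gt$crack_mask), 0.2)
  expect_lt(mean(gt$hole_mask), 0.2)
  s <- true_surface_us_grid(gt)
  expect_true(all(s$heights > 0 & s$heights < p$depth_mm * 1000))
})

test_that("amplitudes exceeding the imaged depth are rejected", {
  expect_error(generate_ground_truth(quick_params(waviness_amplitude = 900)),
               "depth")
})

test_that("noise-free US volume puts the echo peak on the true surface", {
  p <- clean_params(seed = 5)
  gt <- generate_ground_truth(p)
  us <- simulate_us_volume(gt)
  vol <- us$volume
  true_s <- true_surface_us_grid(gt)
  dz <- vol$spacing[2]
  # per-column argmax in the tidemark neighbourhood vs the true surface
  for (i in c(1L, n_frames(vol) %/% 2L)) {
    rows <- apply(vol$intensities[i, , ], 2L, which.max)
    # exclude the cartilage band by restricting to below its reach
    expect_lt(max(abs((rows - 1) * dz - true_s$heights[i, ])), dz + 1e-9)
  }
})

test_that("saline voxels never exceed the noise floor", {
  p <- quick_params(seed = 6)
  gt <- generate_ground_truth(p)
  us <- simulate_us_volume(gt)
  sal <- saline_rows_from_approx(us$volume, us$approx)
  expect_true(all(us$volume$intensities[, sal, ] <= p$noise_floor))
})

test_that("crack columns carry no echo above the noise floor near the surface", {
  p <- quick_params(crack_fraction = 0.08, seed = 7)
  gt <- generate_ground_truth(p)
  us <- simulate_us_volume(gt)
  vol <- us$volume
  s <- true_surface_us_grid(gt)
  dz <- vol$spacing[2]
  ck <- which(gt$crack_mask, arr.ind = TRUE)
  for (r in seq_len(min(40L, nrow(ck)))) {
    i <- ck[r, 1]; j <- ck[r, 2]
    win <- round(s$heights[i, j] / dz) + 1 + (-8:8)
    win <- win[win >= 1 & win <= n_depth(vol)]
    expect_true(all(vol$intensities[i, win, j] <= p$noise_floor))
  }
})

test_that("noise-free CT volume turns calcified exactly below the surface", {
  p <- clean_params(seed = 8)
  gt <- generate_ground_truth(p)
  ct <- simulate_ct_volume(gt)
  truth <- attr(ct, "ct_surface")
  h <- ct$spacing[2]
  lvl <- (p$ct_bone_level + p$ct_background) / 2
  for (i in c(3L, n_frames(ct) %/% 2L)) {
    first <- apply(ct$intensities[i, , ] > lvl, 2L, function(cl) which(cl)[1])
    z <- (first - 1) * h
    expect_lt(max(abs(z - truth$heights[i, ])), h + 1e-9)
  }
})

test_that("perforation columns have no calcified voxel below the interface", {
  p <- clean_params(hole_fraction = 0.05, seed = 10)
  gt <- generate_ground_truth(p)
  ct <- simulate_ct_volume(gt)
  lvl <- (p$ct_bone_level + p$ct_background) / 2
  hk <- which(erode1(gt$hole_mask), arr.ind = TRUE)   # strict channel interior
  # channel axis follows the mean plane; at the hole centre column the whole
  # line below the local surface is inside the channel for small slopes
  truth <- attr(ct, "ct_surface")
  z <- (seq_len(n_depth(ct)) - 1) * ct$spacing[2]
  for (r in seq_len(min(30L, nrow(hk)))) {
    i <- hk[r, 1]; j <- hk[r, 2]
    win <- which(abs(z - truth$heights[i, j]) <= 60)
    expect_true(all(ct$intensities[i, win, j] < lvl))
  }
})
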