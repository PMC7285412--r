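test_that("polynomial references reproduce members of their own basis exactly", {
  x <- seq(0, 1000, length.out = 20); y <- seq(0, 900, length.out = 15)
  plane <- surface_grid(outer(y, x, function(y, x) 100 + 0.05 * x - 0.02 * y),
                        spacing = c(y[2], x[2]))
  f1 <- fit_reference_surface(plane, 1)
  expect_lt(max(abs(plane$heights - f1$fitted)), 1e-9)
  p5 <- surface_grid(outer(y / 900, x / 1000, function(v, u)
    5 + u - 2 * v + 3 * u^2 * v^3 + u^5 - v^5 + u^2 * v^2),
    spacing = c(y[2], x[2]))
  f5 <- fit_reference_surface(p5, 5)
  expect_lt(max(abs(p5$heights - f5$fitted)), 1e-9)
})

test_that("order-1 residuals of plane + sinusoid equal the sinusoid", {
  # midpoint-sampled cosine over whole periods: orthogonal to {1, x, y}
  dx <- 500 / 15
  x <- (seq_len(60) - 0.5) * dx
  y <- (seq_len(40) - 0.5) * 30
  sine <- outer(y, x, function(y, x) 25 * cos(2 * pi * x / 500))
  s <- surface_grid(outer(y, x, function(y, x) 40 + 0.03 * x + 0.01 * y) + sine,
                    spacing = c(30, dx), origin = c(15, dx / 2))
  f <- fit_reference_surface(s, 1)
  expect_lt(max(abs((s$heights - f$fitted) - sine)), 1e-9)
})

test_that("Sa and Sq follow their closed forms on symmetric deviations", {
  h <- matrix(c(7, -7, 7, -7), 2, 2) + 100
  s <- surface_grid(h, spacing = c(1, 1))
  ref <- list(order = 1L, fitted = matrix(100, 2, 2))
  class(ref) <- "reference_surface_fit"
  expect_equal(sa_index(s, ref), 7)
  expect_equal(sq_index(s, ref), 7)
  flat <- surface_grid(matrix(100, 2, 2), spacing = c(1, 1))
  expect_equal(sa_index(flat, ref), 0)
  bad <- list(order = 1L, fitted = matrix(0, 3, 3))
  class(bad) <- "reference_surface_fit"
  expect_error(sa_index(s, bad), "shape")
  expect_error(sq_index(s, bad), "shape")
})

test_that("Sa and Sq match the brute-force double-loop summation", {
  set.seed(55)
  s <- random_surface(11, 13)
  for (ord in c(1, 5)) {
    f <- fit_reference_surface(s, ord)
    expect_equal(sa_index(s, f), sa_brute(s$heights, f$fitted), tolerance = 1e-12)
    expect_equal(sq_index(s, f), sq_brute(s$heights, f$fitted), tolerance = 1e-12)
  }
})

test_that("smoothness indices obey Sa <= Sq, nesting, and invariances", {
  set.seed(56)
  for (r in 1:20) {
    s <- random_surface()
    pan <- smoothness_panel(s)
    expect_lte(pan$SWa, pan$SWq + 1e-12)
    expect_lte(pan$SRa, pan$SRq + 1e-12)
    expect_lte(pan$SRq, pan$SWq + 1e-12)       # order-5 basis nests order-1
    s2 <- surface_grid(s$heights + 137.5, s$spacing)
    expect_equal(smoothness_panel(s2), pan, tolerance = 1e-8)
    tiltfield <- outer(surface_y(s), surface_x(s),
                       function(y, x) 0.04 * x - 0.03 * y)
    s3 <- surface_grid(s$heights + tiltfield, s$spacing)
    pan3 <- smoothness_panel(s3)
    expect_equal(pan3$SWa, pan$SWa, tolerance = 1e-6)
    expect_equal(pan3$SWq, pan$SWq, tolerance = 1e-6)
  }
})

test_that("a planar surface scores zero on every index", {
  x <- seq(0, 500, length.out = 25); y <- seq(0, 480, length.out = 13)
  s <- surface_grid(outer(y, x, function(y, x) 10 + 0.1 * x + 0.05 * y),
                    spacing = c(y[2], x[2]))
  pan <- smoothness_panel(s)
  expect_lt(max(abs(unlist(pan))), 1e-9)
})

test_that("generator roughness drives SRa monotonically at matched seeds", {
  sras <- vapply(c(10, 25, 40), function(amp) {
    s <- generate_ground_truth_surface(clean_params(roughness_amplitude = amp,
                                                    seed = 61))
    smoothness_panel(s)$SRa
  }, numeric(1))
  expect_true(all(diff(sras) > 0))
})

test_that("the Pearson report reproduces hand-computed correlations", {
  x <- c(1, 3, 4, 6, 8)
  expect_equal(pearson_report(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_report(x, -x)$r, -1)
  y <- c(2, 5, 4, 9, 8)
  # longhand: r = sum((x - mx)(y - my)) / sqrt(sum(x - mx)^2 sum(y - my)^2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 3)
  rep <- pearson_report(x, y)
  expect_equal(rep$r, r_hand, tolerance = 1e-12)
  expect_equal(rep$p, p_hand, tolerance = 1e-12)
  expect_error(pearson_report(x, rep(1, 5)), "variance")
  expect_error(pearson_report(1:2, 2:3), "3 pairs")
})

test_that("rank-deficient designs and undersized grids are rejected", {
  tiny <- surface_grid(matrix(1:4 + 0.5, 2, 2), spacing = c(1, 1))
  expect_error(fit_reference_surface(tiny, 5), "not enough")
})
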