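test_that("rigid transforms validate, compose and invert correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(5, -2, 1))
  rt <- compose_transform(invert_transform(tr), tr)
  expect_lt(max(abs(rt$R - diag(3))), 1e-12)
  expect_lt(max(abs(rt$t)), 1e-12)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(apply_transform(invert_transform(tr), apply_transform(tr, p)), p)
})

test_that("surface grids convert to point clouds with exact coordinates", {
  s <- surface_grid(matrix(c(10, 20, 30, 40), 2, 2), spacing = c(32, 15))
  pts <- surface_to_pointcloud(s)
  expect_equal(nrow(pts), 4)
  expect_equal(pts[1, ], c(0, 0, 10))
  expect_equal(pts[4, ], c(15, 32, 40))
  s$valid[1, 1] <- FALSE
  expect_equal(nrow(surface_to_pointcloud(s, exclude_invalid = TRUE)), 3)
  s2 <- surface_grid(s$heights, spacing = c(64, 30))
  expect_equal(surface_to_pointcloud(s2)[4, 1:2], c(30, 64))
})

test_that("surface meshing produces 2(M-1)(N-1) consistent triangles", {
  s <- surface_grid(matrix(c(10, 20, 30, 40), 2, 2), spacing = c(32, 15))
  m <- surface_to_mesh(s)
  expect_equal(nrow(m$faces), 2)
  s3 <- random_surface(7, 9)
  expect_equal(nrow(surface_to_mesh(s3)$faces), 2 * 6 * 8)
  sp <- surface_grid(outer(1:4, 1:5, function(i, j) 3 * i - 2 * j),
                     spacing = c(10, 10))
  mp <- surface_to_mesh(sp)
  nrm <- t(apply(mp$faces, 1, function(f) {
    a <- mp$vertices[f[2], ] - mp$vertices[f[1], ]
    b <- mp$vertices[f[3], ] - mp$vertices[f[1], ]
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    n / sqrt(sum(n^2))
  }))
  expect_lt(max(apply(nrm, 2, function(x) diff(range(x)))), 1e-12)
})

test_that("ICP is a fixed point on identical clouds", {
  set.seed(11)
  cl <- cbind(runif(500, 0, 1000), runif(500, 0, 1000), rnorm(500, 100, 20))
  res <- icp_register(cl, cl)
  expect_lt(max(abs(res$transform$R - diag(3))), 1e-9)
  expect_lt(max(abs(res$transform$t)), 1e-9)
  expect_lt(res$rms, 1e-9)
  expect_true(res$converged)
})

test_that("ICP recovers pure translations and small rotations", {
  set.seed(12)
  p <- clean_params(roughness_amplitude = 40, seed = 13)
  cl <- surface_to_pointcloud(generate_ground_truth_surface(p))
  cl <- cl[sample(nrow(cl), 3000), ]
  tr1 <- rigid_transform(diag(3), c(100, -50, 20))
  r1 <- icp_register(cl, apply_transform(tr1, cl), init = "centroid")
  expect_lt(sqrt(sum((r1$transform$t - tr1$t)^2)), 0.1)
  expect_lt(rotation_angle_deg(r1$transform$R), 0.001)

  tr2 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 1), c(250, 120, -40))
  r2 <- icp_register(cl, apply_transform(tr2, cl), init = "centroid")
  derr <- compose_transform(invert_transform(tr2), r2$transform)
  expect_lt(sqrt(sum(derr$t^2)), 0.1)
  expect_lt(rotation_angle_deg(derr), 0.001)
})

test_that("ICP rejects degenerate sources and records a non-increasing RMS", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icp_register(line, line), "collinear")
  set.seed(14)
  cl <- cbind(runif(800, 0, 500), runif(800, 0, 500), rnorm(800, 0, 15))
  tgt <- apply_transform(rigid_transform(rotation_about_axis(c(1, 1, 0), 2),
                                         c(40, -30, 10)), cl)
  res <- icp_register(cl, tgt, init = "centroid")
  expect_true(all(diff(res$rms_history) <= 1e-9))
  d <- abs(diff(res$rms_history))
  expect_lt(d[length(d)], 0.01)      # the 0.01 um stopping rule fired
})

test_that("point-to-mesh distances match trivial geometry", {
  s <- surface_grid(matrix(0, 5, 5), spacing = c(10, 10))
  mesh <- surface_to_mesh(s)
  expect_equal(point_mesh_distance(matrix(c(20, 20, 10), 1), mesh), 10)
  on_mesh <- surface_to_pointcloud(s)
  expect_lt(max(point_mesh_distance(on_mesh, mesh)), 1e-12)
  d <- mean_surface_discrepancy(rbind(c(5, 5, 10), c(15, 15, 20), c(25, 25, 30)),
                                mesh)
  expect_equal(d$d_diff, 20)
  expect_equal(d$sd, 10)
})

test_that("point-to-mesh distance matches the brute-force all-triangle oracle", {
  set.seed(15)
  s <- random_surface(6, 7)
  mesh <- surface_to_mesh(s)          # 60 triangles
  pts <- cbind(runif(40, -30, 160), runif(40, -30, 200),
               runif(40, min(s$heights) - 50, max(s$heights) + 50))
  expect_equal(point_mesh_distance(pts, mesh), point_mesh_dist_oracle(pts, mesh),
               tolerance = 1e-9)
})

test_that("the discrepancy is invariant under a common rigid motion", {
  set.seed(16)
  s <- random_surface(8, 8)
  mesh <- surface_to_mesh(s)
  pts <- surface_to_pointcloud(s) + cbind(rnorm(64, 0, 5), rnorm(64, 0, 5),
                                          rnorm(64, 0, 5))
  d0 <- mean_surface_discrepancy(pts, mesh)$d_diff
  tr <- rigid_transform(rotation_about_axis(c(1, 2, 3), 25), c(100, -40, 60))
  mesh2 <- tri_mesh(apply_transform(tr, mesh$vertices), mesh$faces)
  d1 <- mean_surface_discrepancy(apply_transform(tr, pts), mesh2)$d_diff
  expect_equal(d0, d1, tolerance = 1e-6)
})

test_that("coarse heightmap alignment finds the lateral offset of a cropped patch", {
  p <- clean_params(field_size_mm = 2.5, roughness_amplitude = 35, seed = 17)
  s <- generate_ground_truth_surface(p)
  patch <- crop_surface(s, c(600, 1700), c(500, 1600))
  patch0 <- surface_grid(patch$heights, patch$spacing)   # origin reset to 0
  tr <- coarse_align_surfaces(patch0, s, step_um = 100, range_um = 2000)
  expect_lt(abs(tr$t[1] - 600), 80)
  expect_lt(abs(tr$t[2] - 512), 80)    # first elevational node inside the crop

  expect_lt(abs(tr$t[3]), 25)
})
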