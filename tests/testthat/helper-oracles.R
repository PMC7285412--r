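# Small-disk parameter presets and independent oracles used across tests.

quick_params <- function(...) {
  do.call(synth_params, utils::modifyList(list(field_size_mm = 1.5), list(...)))
}

clean_params <- function(...) {
  base <- list(field_size_mm = 1.5, noise_floor = 0, speckle = 0,
               ct_noise_sd = 0, crack_fraction = 0, hole_fraction = 0,
               tilt_deg = 0, max_rot_deg = 0, max_trans_um = 0)
  do.call(synth_params, utils::modifyList(base, list(...)))
}

# Brute-force Otsu: exhaustive scan of every histogram cut maximizing the
# between-class variance, written directly from the definition.
otsu_brute <- function(x, n_bins = 256L) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  best <- -Inf; best_cut <- NA_integer_
  for (cut in seq_len(n_bins - 1L)) {
    n0 <- sum(cnt[1:cut]); n1 <- sum(cnt) - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(cnt[1:cut] * mids[1:cut]) / n0
    m1 <- sum(cnt[(cut + 1):n_bins] * mids[(cut + 1):n_bins]) / n1
    v <- (n0 / sum(cnt)) * (n1 / sum(cnt)) * (m0 - m1)^2
    if (v > best + 1e-15) { best <- v; best_cut <- cut }
  }
  breaks[best_cut + 1L]
}

# Independent point-to-triangle distance: project onto the triangle plane,
# accept if barycentric-inside, else minimize over the three edge segments.
point_tri_dist_oracle <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(1, max(0, t))
    sqrt(sum((u + t * d - p)^2))
  }
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n <- cr(b - a, c - a)
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n
  # barycentric test of q
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(abs(sum((p - a) * n)))
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
}

point_mesh_dist_oracle <- function(points, mesh) {
  apply(points, 1L, function(p) {
    min(apply(mesh$faces, 1L, function(f) {
      point_tri_dist_oracle(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                            mesh$vertices[f[3], ])
    }))
  })
}

# Double-loop Sa/Sq straight from the definitions.
sa_brute <- function(h, ref) {
  s <- 0
  for (i in seq_len(nrow(h))) for (j in seq_len(ncol(h)))
    s <- s + abs(h[i, j] - ref[i, j])
  s / (nrow(h) * ncol(h))
}

sq_brute <- function(h, ref) {
  s <- 0
  for (i in seq_len(nrow(h))) for (j in seq_len(ncol(h)))
    s <- s + (h[i, j] - ref[i, j])^2
  sqrt(s / (nrow(h) * ncol(h)))
}

# 8-neighbour dilation / erosion of a logical mask; perforation boundary
# voxels are partial-volume ambiguous, so exact-recovery checks use the
# dilated mask as exclusion zone and the eroded mask as guaranteed interior
shift_mat <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  si <- seq_len(nrow(m)) - di; sj <- seq_len(ncol(m)) - dj
  ok_i <- si >= 1 & si <= nrow(m); ok_j <- sj >= 1 & sj <= ncol(m)
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

dilate1 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) out <- out | shift_mat(m, di, dj)
  out
}

erode1 <- function(m) !dilate1(!m)

# random smooth-ish surface grid for property tests
random_surface <- function(m = 12L, n = 15L, dy = 30, dx = 20) {
  x <- seq(0, 1, length.out = n); y <- seq(0, 1, length.out = m)
  h <- outer(y, x, function(y, x)
    50 * x - 30 * y + 20 * sin(2 * pi * (runif(1) + 2 * x)) +
      10 * cos(2 * pi * (runif(1) + 3 * y + x))) +
    matrix(rnorm(m * n, sd = 3), m, n)
  surface_grid(h, spacing = c(dy, dx))
}
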