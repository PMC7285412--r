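## 1-nearest-neighbour indices of `query` rows in `ref` rows.
## Uses RANN's k-d tree when available; otherwise a blocked exact search.
nn_index <- function(ref, query) {
  if (requireNamespace("RANN", quietly = TRUE)) {
    return(RANN::nn2(ref, query, k = 1L)$nn.idx[, 1L])
  }
  n <- nrow(query)
  idx <- integer(n)
  rn2 <- rowSums(ref^2)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn2, "+") - 2 * tcrossprod(q, ref)
    idx[s:e] <- max.col(-d2, ties.method = "first")
  }
  idx
}

## closed-form least-squares rigid fit src -> tgt (cross-covariance + SVD)
kabsch <- function(src, tgt) {
  ms <- colMeans(src); mt <- colMeans(tgt)
  H <- crossprod(sweep(src, 2L, ms), sweep(tgt, 2L, mt))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, mt - as.numeric(R %*% ms))
}

## bilinear interpolation of surface heights at physical (x, y); NA outside
interp_surface <- function(s, x, y) {
  gx <- surface_x(s); gy <- surface_y(s)
  fx <- (x - gx[1L]) / s$spacing[2L] + 1
  fy <- (y - gy[1L]) / s$spacing[1L] + 1
  j <- floor(fx); i <- floor(fy)
  wx <- fx - j; wy <- fy - i
  ok <- i >= 1 & i + 1 <= nrow(s$heights) & j >= 1 & j + 1 <= ncol(s$heights)
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    i <- i[ok]; j <- j[ok]; wxo <- wx[ok]; wyo <- wy[ok]
    h <- s$heights
    out[ok] <- (1 - wy[ok]) * ((1 - wxo) * h[cbind(i, j)] + wxo * h[cbind(i, j + 1)]) +
      wy[ok] * ((1 - wxo) * h[cbind(i + 1, j)] + wxo * h[cbind(i + 1, j + 1)])
  }
  out
}

#' Coarse translational alignment of two heightmap surfaces
#'
#' Surrogate for the manual coarse alignment performed before ICP: an
#' exhaustive search over lateral shifts (grid step `step_um`, range
#' `range_um`) minimizing the mean absolute height mismatch between the
#' shifted source surface and the target surface on their overlap, after
#' removing the median height offset at each shift. Returns a
#' translation-only rigid transform suitable as the `init` of
#' [icp_register()].
#'
#' @param source,target [surface_grid()] objects (the target may extend
#'   beyond the source laterally).
#' @param step_um lateral search step (um).
#' @param range_um maximum lateral shift searched in each direction (um).
#' @param n_sample number of source nodes sampled for the cost (subsampling
#'   keeps the search cheap).
#' @return A [rigid_transform()] with zero rotation.
#' @export
coarse_align_surfaces <- function(source, target, step_um = 100,
                                  range_um = 1500, n_sample = 500L) {
  stopifnot(inherits(source, "surface_grid"), inherits(target, "surface_grid"))
  m <- nrow(source$heights); n <- ncol(source$heights)
  ii <- round(seq(1L, m, length.out = min(m, ceiling(sqrt(n_sample)))))
  jj <- round(seq(1L, n, length.out = min(n, ceiling(sqrt(n_sample)))))
  sx <- surface_x(source)[jj]; sy <- surface_y(source)[ii]
  px <- rep(sx, each = length(ii)); py <- rep(sy, times = length(jj))
  pz <- as.vector(source$heights[ii, jj])
  shifts <- seq(-range_um, range_um, by = step_um)
  best <- c(Inf, 0, 0, 0)
  for (dx in shifts) for (dy in shifts) {
    tz <- interp_surface(target, px + dx, py + dy)
    ok <- !is.na(tz)
    if (mean(ok) < 0.8) next             # demand substantial overlap
    dzv <- tz[ok] - pz[ok]
    dz <- median(dzv)
    cost <- mean(abs(dzv - dz))
    if (cost < best[1L]) best <- c(cost, dx, dy, dz)
  }
  if (!is.finite(best[1L])) stop("no overlapping shift found in search range")
  rigid_transform(diag(3), best[2:4])
}

#' Rigid ICP registration of a point cloud onto a reference
#'
#' Iterative closest point: alternates nearest-neighbour correspondence with
#' the closed-form least-squares rigid fit (cross-covariance/SVD), until the
#' RMS correspondence distance changes by less than `tol` between two
#' iterations (default 0.01 um) or `max_iter` is reached.
#'
#' @param source n x 3 point matrix (um), the cloud to be moved.
#' @param target reference: an m x 3 point matrix or a [tri_mesh()]
#'   (its vertices are used for correspondence).
#' @param init initial [rigid_transform()], `"identity"`, or `"centroid"`
#'   (translation aligning the centroids, the coarse-alignment surrogate).
#' @param tol stopping threshold on the iteration-to-iteration RMS
#'   difference (um).
#' @param max_iter maximum number of iterations.
#' @param trim fraction of closest correspondences kept in the fit
#'   (1 = plain ICP, no rejection).
#' @return An object of class `icp_result`: `transform` (cumulative,
#'   including `init`), `rms` (final RMS correspondence distance, um),
#'   `rms_history`, `iterations`, `converged`.
#' @export
icp_register <- function(source, target, init = "identity", tol = 0.01,
                         max_iter = 200L, trim = 1) {
  source <- as_points(source)
  tgt <- if (inherits(target, "tri_mesh")) target$vertices else as_points(target)
  if (nrow(source) < 3L) stop("source needs at least 3 points")
  sv <- svd(sweep(source, 2L, colMeans(source)))$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1))
    stop("source points are collinear or coincident; registration is degenerate")
  stopifnot(trim > 0, trim <= 1)

  Tcur <- if (inherits(init, "rigid_transform")) init
  else if (identical(init, "centroid"))
    rigid_transform(diag(3), colMeans(tgt) - colMeans(source))
  else identity_transform()

  rms_history <- numeric(0)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cur <- apply_transform(Tcur, source)
    idx <- nn_index(tgt, cur)
    d <- sqrt(rowSums((cur - tgt[idx, , drop = FALSE])^2))
    keep <- if (trim < 1) order(d)[seq_len(max(3L, floor(trim * length(d))))]
    else seq_along(d)
    inc <- kabsch(cur[keep, , drop = FALSE], tgt[idx[keep], , drop = FALSE])
    Tcur <- compose_transform(inc, Tcur)
    cur <- apply_transform(Tcur, source)
    rms <- sqrt(mean(rowSums((cur - tgt[idx, , drop = FALSE])^2)))
    rms_history <- c(rms_history, rms)
    if (is.finite(prev) && abs(prev - rms) < tol) { converged <- TRUE; break }
    prev <- rms
  }
  structure(list(transform = Tcur, rms = rms_history[length(rms_history)],
                 rms_history = rms_history, iterations = it,
                 converged = converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> %d iterations, final RMS %.4f um, converged: %s\n",
              x$iterations, x$rms, x$converged))
  invisible(x)
}

#' Unsigned distances from points to a triangle mesh
#'
#' Exact Euclidean distance from each point to its nearest point on any
#' triangle (interior, edge, or vertex), accelerated by lateral binning of
#' the triangles.
#'
#' @param points n x 3 matrix (um).
#' @param mesh a [tri_mesh()].
#' @return Numeric vector of distances (um).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- as_points(points)
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(points) == 0L) stop("empty point set")
  cpp_point_mesh_dist(points, mesh$vertices, mesh$faces)
}

#' Mean surface discrepancy between a point cloud and a reference surface
#'
#' The average distance discrepancy
#' `D_diff = (1/N) * sum_i d(p_i, s_ref)`, where `d` is the unsigned
#' Euclidean distance from point `i` to the reference triangulated surface.
#' The standard deviation of the per-point distances is reported alongside.
#'
#' @param points n x 3 point matrix (um), e.g. the registered US tidemark
#'   cloud.
#' @param reference a [tri_mesh()] reference surface, e.g. the micro-CT
#'   tidemark mesh.
#' @return A list with `d_diff` (mean distance, um), `sd`, and `distances`.
#' @export
mean_surface_discrepancy <- function(points, reference) {
  d <- point_mesh_distance(points, reference)
  list(d_diff = mean(d), sd = sd(d), distances = d)
}
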