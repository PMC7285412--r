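#' Heightmap surface on a regular lateral grid
#'
#' Tidemark surface heights `z(i, j)` in micrometres, row `i` along the
#' elevational axis (one row per frame), column `j` along the lateral axis.
#' `valid` is `FALSE` where the height was filled by interpolation over a
#' crack or hole rather than detected.
#'
#' @param heights numeric matrix of heights (um), `n_frames x n_lateral`.
#' @param spacing length-2 numeric `(elevational dy, lateral dx)` um.
#' @param valid logical matrix, same shape as `heights`.
#' @param origin length-2 numeric lateral offset `(y0, x0)` um.
#' @return An object of class `surface_grid`.
#' @export
surface_grid <- function(heights, spacing, valid = NULL, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  if (length(heights) == 0L) stop("empty surface grid")
  if (!all(is.finite(heights))) stop("surface heights must be finite")
  stopifnot(length(spacing) == 2L, all(spacing > 0), length(origin) == 2L)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(heights), ncol(heights))
  if (!identical(dim(valid), dim(heights)))
    stop("valid mask must have the same shape as heights")
  structure(list(heights = unname(heights), spacing = as.numeric(spacing),
                 valid = unname(valid), origin = as.numeric(origin)),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d nodes, spacing (%g, %g) um, %d interpolated\n",
              nrow(x$heights), ncol(x$heights), x$spacing[1], x$spacing[2],
              sum(!x$valid)))
  invisible(x)
}

surface_x <- function(s) s$origin[2L] + (seq_len(ncol(s$heights)) - 1) * s$spacing[2L]
surface_y <- function(s) s$origin[1L] + (seq_len(nrow(s$heights)) - 1) * s$spacing[1L]

#' Crop a surface grid to a lateral window
#'
#' Keeps the grid nodes whose lateral coordinates fall inside `xlim` and
#' `ylim` (um). Used to restrict the reference-modality surface to the
#' footprint actually imaged by the other modality before comparing
#' smoothness indices.
#'
#' @param s a [surface_grid()].
#' @param xlim,ylim length-2 numeric ranges (um).
#' @return A [surface_grid()] on the cropped grid.
#' @export
crop_surface <- function(s, xlim, ylim) {
  stopifnot(inherits(s, "surface_grid"))
  jj <- which(surface_x(s) >= xlim[1] & surface_x(s) <= xlim[2])
  ii <- which(surface_y(s) >= ylim[1] & surface_y(s) <= ylim[2])
  if (length(ii) < 2L || length(jj) < 2L) stop("crop window too small")
  surface_grid(s$heights[ii, jj, drop = FALSE], s$spacing,
               valid = s$valid[ii, jj, drop = FALSE],
               origin = c(surface_y(s)[ii[1L]], surface_x(s)[jj[1L]]))
}

#' Convert a surface grid to a 3D point cloud
#'
#' One point per grid node at `(x = x0 + (j-1) dx, y = y0 + (i-1) dy, z(i,j))`,
#' all in micrometres. Points are emitted column-major (j fastest varying in
#' memory order of the heights matrix).
#'
#' @param s a [surface_grid()].
#' @param exclude_invalid drop nodes whose heights were interpolated?
#' @return n x 3 numeric matrix with columns `(x, y, z)`.
#' @export
surface_to_pointcloud <- function(s, exclude_invalid = FALSE) {
  stopifnot(inherits(s, "surface_grid"))
  x <- surface_x(s); y <- surface_y(s)
  pts <- cbind(x = rep(x, each = nrow(s$heights)),
               y = rep(y, times = ncol(s$heights)),
               z = as.vector(s$heights))
  if (exclude_invalid) pts <- pts[as.vector(s$valid), , drop = FALSE]
  if (nrow(pts) == 0L) stop("no points left in cloud")
  unname(pts)
}

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix (um).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as_points(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(faces) == 3L)
  storage.mode(faces) <- "integer"
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  if (any(rowSums(cr^2) == 0)) stop("degenerate (zero-area) triangle in mesh")
  structure(list(vertices = vertices, faces = unname(faces)), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Triangulate a surface grid
#'
#' Two triangles per grid cell with consistent winding (counter-clockwise
#' seen from above, i.e. from negative `z`).
#'
#' @param s a [surface_grid()] with at least 2 x 2 nodes.
#' @return A [tri_mesh()] with `2 (M-1) (N-1)` triangles.
#' @export
surface_to_mesh <- function(s) {
  stopifnot(inherits(s, "surface_grid"))
  m <- nrow(s$heights); n <- ncol(s$heights)
  if (m < 2L || n < 2L) stop("need at least a 2 x 2 grid to triangulate")
  v <- surface_to_pointcloud(s, exclude_invalid = FALSE)
  idx <- function(i, j) (j - 1L) * m + i        # column-major node id
  i <- rep(seq_len(m - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = m - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
  f2 <- cbind(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  tri_mesh(v, rbind(f1, f2))
}
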