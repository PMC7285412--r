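#' Volumetric image with physical spacing
#'
#' A 3D grayscale grid indexed `[frame, depth_row, lateral_col]` with per-axis
#' spacing in micrometres. Frame index runs along the elevational (scan) axis
#' `y`, depth rows along `z` (increasing downward), lateral columns along `x`.
#' The physical coordinate of voxel centre `(i, k, j)` (1-based indices) is
#' `origin + (i-1, k-1, j-1) * spacing` on the `(y, z, x)` axes.
#'
#' @param intensities 3D numeric array, dim `(n_frames, n_depth, n_lateral)`.
#' @param spacing length-3 numeric, `(elevational, axial, lateral)` um.
#' @param origin length-3 numeric, physical offset `(y0, z0, x0)` um.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            length(spacing) == 3L, all(spacing > 0), all(is.finite(spacing)),
            length(origin) == 3L, all(is.finite(origin)))
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  structure(list(intensities = intensities,
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume3d> %d frames x %d depth rows x %d columns, spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$intensities)

n_frames  <- function(vol) dim(vol$intensities)[1L]
n_depth   <- function(vol) dim(vol$intensities)[2L]
n_lateral <- function(vol) dim(vol$intensities)[3L]

## physical depth (z, um) of each depth row
depth_coords <- function(vol) {
  vol$origin[2L] + (seq_len(n_depth(vol)) - 1) * vol$spacing[2L]
}

lateral_coords <- function(vol) {
  vol$origin[3L] + (seq_len(n_lateral(vol)) - 1) * vol$spacing[3L]
}

frame_coords <- function(vol) {
  vol$origin[1L] + (seq_len(n_frames(vol)) - 1) * vol$spacing[1L]
}

## depth row index (possibly fractional, 1-based) for physical depth z um
depth_to_row <- function(vol, z_um) (z_um - vol$origin[2L]) / vol$spacing[2L] + 1
row_to_depth <- function(vol, row)  vol$origin[2L] + (row - 1) * vol$spacing[2L]
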