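#' Estimate the noise level from the saline region
#'
#' The noise level is the reference signal in the saline solution, i.e. the
#' dark region above the cartilage surface. The threshold is
#' `mean + k * SD` of the intensities in the given depth rows, with the
#' population SD (so a constant region gives exactly its value).
#'
#' @param vol a [volume3d()].
#' @param saline_rows integer vector of depth-row indices lying in saline.
#' @param k number of SDs above the mean (default 3).
#' @return Scalar threshold (same grayscale units as the volume).
#' @export
estimate_noise_level <- function(vol, saline_rows, k = 3) {
  stopifnot(inherits(vol, "volume3d"))
  saline_rows <- as.integer(saline_rows)
  if (length(saline_rows) == 0L) stop("saline region is empty")
  if (min(saline_rows) < 1L || max(saline_rows) > n_depth(vol))
    stop("saline rows outside the volume")
  x <- vol$intensities[, saline_rows, , drop = FALSE]
  m <- mean(x)
  m + k * sqrt(mean((x - m)^2))
}

## first (shallowest) strict local maximum above `thr` in rows lo..hi of `v`;
## plateaus resolve to their shallowest index; returns NA_integer_ if none
find_first_peak <- function(v, lo, hi, thr) {
  n <- length(v)
  for (k in lo:hi) {
    if (v[k] <= thr) next
    right <- if (k < n) v[k + 1L] else -Inf
    if (v[k] < right) next
    if (k == 1L) return(k)
    if (v[k] > v[k - 1L]) return(k)
    if (v[k] == v[k - 1L] && k == lo) return(k)   # plateau entering the window
  }
  NA_integer_
}

#' Extract the tidemark profile from one B-scan frame
#'
#' For every lateral column, searches the first (shallowest) peak above the
#' noise threshold within a window of `window_px` pixels centred at the
#' approximate (manually drawn) profile row. Columns with no peak above the
#' threshold are flagged as cracks and left `NA` for interpolation.
#'
#' @param frame numeric matrix, depth rows x lateral columns.
#' @param approx_rows numeric vector of approximate profile rows, one per
#'   column (1-based; may be fractional, it is rounded).
#' @param threshold noise threshold from [estimate_noise_level()].
#' @param window_px search window height in pixels (default 20, ~0.30 mm at
#'   15 um pixels).
#' @param subpixel apply 3-point parabolic refinement around the peak row?
#' @return A list with `rows` (numeric, NA at cracks) and `crack` (logical).
#' @export
extract_profile_2d <- function(frame, approx_rows, threshold, window_px = 20L,
                               subpixel = FALSE) {
  frame <- as.matrix(frame)
  nz <- nrow(frame); nx <- ncol(frame)
  if (window_px < 3L) stop("window_px must be at least 3")
  stopifnot(length(approx_rows) == nx)
  a <- round(approx_rows)
  if (any(a < 1L) || any(a > nz)) stop("approximate profile outside the frame")
  half <- window_px %/% 2L
  rows <- rep(NA_real_, nx)
  for (j in seq_len(nx)) {
    lo <- max(1L, a[j] - half)
    hi <- min(nz, lo + window_px - 1L)
    lo <- max(1L, hi - window_px + 1L)
    k <- find_first_peak(frame[, j], lo, hi, threshold)
    if (!is.na(k)) {
      if (subpixel && k > 1L && k < nz) {
        y0 <- frame[k - 1L, j]; y1 <- frame[k, j]; y2 <- frame[k + 1L, j]
        den <- y0 - 2 * y1 + y2
        rows[j] <- if (den < 0) k + 0.5 * (y0 - y2) / den else k
      } else rows[j] <- k
    }
  }
  list(rows = rows, crack = is.na(rows))
}

#' Fill crack columns by interpolation from neighbours
#'
#' Flagged columns are filled by 1D linear interpolation between the nearest
#' valid neighbours; gaps at the profile edges are filled by extending the
#' nearest valid value.
#'
#' @param profile numeric vector of depths (rows or um).
#' @param flags logical vector, `TRUE` where the value must be filled.
#' @return Numeric vector with no missing values.
#' @export
interpolate_gaps <- function(profile, flags) {
  stopifnot(length(profile) == length(flags))
  if (all(flags)) stop("all columns flagged; nothing to interpolate from")
  if (!any(flags)) return(profile)
  idx <- which(!flags)
  out <- profile
  if (length(idx) == 1L) {
    out[flags] <- profile[idx]
  } else {
    out[flags] <- approx(idx, profile[idx], xout = which(flags), rule = 2)$y
  }
  out
}

#' Extract the 3D tidemark surface from a B-scan stack
#'
#' Applies [extract_profile_2d()] and [interpolate_gaps()] frame by frame:
#' a 2D tidemark profile is extracted from every B-scan and the profiles in
#' sequence form the 3D surface. Heights are converted to micrometres via the
#' axial spacing; the validity mask records crack columns.
#'
#' @param vol a [volume3d()] B-scan stack.
#' @param approx matrix of approximate tidemark depths (um),
#'   frames x columns.
#' @param threshold noise threshold from [estimate_noise_level()].
#' @inheritParams extract_profile_2d
#' @return A [surface_grid()] (elevational rows, lateral columns).
#' @export
extract_surface_3d <- function(vol, approx, threshold, window_px = 20L,
                               subpixel = FALSE) {
  stopifnot(inherits(vol, "volume3d"))
  approx <- as.matrix(approx)
  if (!identical(dim(approx), dim(vol$intensities)[c(1L, 3L)]))
    stop("approximate profile must cover every frame and column")
  ny <- n_frames(vol); nx <- n_lateral(vol)
  a_rows <- depth_to_row(vol, approx)
  heights <- matrix(NA_real_, ny, nx)
  valid <- matrix(TRUE, ny, nx)
  for (i in seq_len(ny)) {
    pr <- extract_profile_2d(vol$intensities[i, , ], a_rows[i, ], threshold,
                             window_px = window_px, subpixel = subpixel)
    rows <- interpolate_gaps(pr$rows, pr$crack)
    heights[i, ] <- row_to_depth(vol, rows)
    valid[i, ] <- !pr$crack
  }
  surface_grid(heights, spacing = vol$spacing[c(1L, 3L)], valid = valid,
               origin = c(vol$origin[1L], vol$origin[3L]))
}
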