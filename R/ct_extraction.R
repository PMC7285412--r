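#' Estimate the global tilt of the interface in a micro-CT volume
#'
#' Averages all frames into a single 2D image, finds the per-column interface
#' level on the averaged image (first run of supra-threshold voxels below an
#' Otsu cut), and fits a straight line by least squares. The returned angle
#' is the inclination of the interface in the `(x, z)` frame plane;
#' `rotate_volume(vol, -estimate_tilt(vol))` levels the surface.
#'
#' @param vol a [volume3d()].
#' @param min_run minimum run length of supra-threshold voxels (voxels).
#' @return Tilt angle in degrees.
#' @export
estimate_tilt <- function(vol, min_run = 2L) {
  stopifnot(inherits(vol, "volume3d"))
  img <- apply(vol$intensities, c(2L, 3L), mean)     # depth rows x columns
  thr <- otsu_threshold(img)
  rows <- first_transition_rows(img > thr, min_run)
  ok <- !is.na(rows)
  if (mean(ok) < 0.5) stop("no interface transition found in most columns")
  x <- lateral_coords(vol)[ok]
  z <- row_to_depth(vol, rows[ok])
  slope <- coef(lm(z ~ x))[[2L]]
  atan(slope) * 180 / pi
}

#' Rotate every frame of a volume in-plane
#'
#' Rotates each `(depth, lateral)` frame by `angle_deg` about the frame
#' centre with bilinear resampling; voxels mapped from outside the field are
#' filled with the volume minimum. Positive angles rotate a surface of
#' positive `dz/dx` slope towards horizontal when negated, i.e.
#' `rotate_volume(vol, -estimate_tilt(vol))` levels the interface.
#'
#' @param vol a [volume3d()] with square in-plane voxels.
#' @param angle_deg rotation angle, `|angle| < 15` degrees.
#' @return A rotated [volume3d()] of the same shape.
#' @export
rotate_volume <- function(vol, angle_deg) {
  stopifnot(inherits(vol, "volume3d"))
  if (abs(angle_deg) >= 15) stop("|angle| must be < 15 degrees")
  if (abs(vol$spacing[2L] - vol$spacing[3L]) > 1e-9)
    stop("in-plane voxels must be square for frame rotation")
  if (angle_deg == 0) return(vol)
  nz <- n_depth(vol); nx <- n_lateral(vol)
  th <- angle_deg * pi / 180
  cz <- (nz + 1) / 2; cx <- (nx + 1) / 2
  k <- rep(seq_len(nz), times = nx) - cz          # target pixel offsets
  j <- rep(seq_len(nx), each = nz) - cx
  ## inverse map: source = R(-th) target
  sz <- cos(th) * k - sin(th) * j + cz
  sx <- sin(th) * k + cos(th) * j + cx
  f_z <- floor(sz); f_x <- floor(sx)
  wz <- sz - f_z; wx <- sx - f_x
  inside <- f_z >= 1L & f_z + 1L <= nz & f_x >= 1L & f_x + 1L <= nx
  fill <- min(vol$intensities)
  cl_z <- function(v) pmin(pmax(v, 1L), nz)
  cl_x <- function(v) pmin(pmax(v, 1L), nx)
  i00 <- cbind(cl_z(f_z), cl_x(f_x))
  i10 <- cbind(cl_z(f_z + 1L), i00[, 2L])
  i01 <- cbind(i00[, 1L], cl_x(f_x + 1L))
  i11 <- cbind(i10[, 1L], i01[, 2L])
  out <- vol$intensities
  for (i in seq_len(n_frames(vol))) {
    fr <- vol$intensities[i, , ]
    v <- (1 - wz) * (1 - wx) * fr[i00] + wz * (1 - wx) * fr[i10] +
      (1 - wz) * wx * fr[i01] + wz * wx * fr[i11]
    v[!inside] <- fill
    out[i, , ] <- v
  }
  volume3d(out, vol$spacing, vol$origin)
}

#' Otsu threshold of a volume or image
#'
#' Histogram-based threshold maximizing the between-class variance over
#' `n_bins` equal-width bins spanning the data range; ties are broken toward
#' the lower cut. Binarize with `value > threshold`.
#'
#' @param vol a [volume3d()], or any numeric array/matrix.
#' @param n_bins number of histogram bins (default 256).
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(vol, n_bins = 256L) {
  x <- if (inherits(vol, "volume3d")) vol$intensities else vol
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant input has no Otsu threshold")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  p <- cnt / length(x)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)[-n_bins]
  m0 <- cumsum(p * mids)[-n_bins]
  mT <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mT * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  cut <- which.max(sb)                      # which.max takes the first: lower tie
  breaks[cut + 1L]
}

#' Binarize a volume at a threshold
#'
#' @param vol a [volume3d()].
#' @param threshold scalar; voxels strictly above it become `TRUE`
#'   (calcified tissue).
#' @return An object of class `binary_volume` (fields `mask`, `spacing`,
#'   `origin`).
#' @export
binarize <- function(vol, threshold) {
  stopifnot(inherits(vol, "volume3d"), is.finite(threshold))
  structure(list(mask = vol$intensities > threshold,
                 spacing = vol$spacing, origin = vol$origin),
            class = "binary_volume")
}

## per column, 1-based row of the first TRUE that starts a run of >= min_run;
## works on a logical matrix (depth rows x columns); NA where none
first_transition_rows <- function(mask, min_run = 2L) {
  mask <- as.matrix(mask)
  run <- mask
  if (min_run > 1L) {
    for (r in seq_len(min_run - 1L))
      run <- run & rbind(mask[-seq_len(r), , drop = FALSE],
                         matrix(FALSE, r, ncol(mask)))
  }
  apply(run, 2L, function(col) {
    k <- which(col)
    if (length(k)) k[1L] else NA_integer_
  })
}

#' Extract the 3D tidemark surface from a binarized micro-CT volume
#'
#' Per vertical line, the surface is the first abrupt change - the first
#' background-to-calcified transition scanning from shallow - required to
#' start a run of at least `min_run` calcified voxels (so isolated bright
#' noise voxels are ignored). Columns whose transition lies further than
#' `window_um` from the local median interface level (a running median over
#' `median_k` neighbouring columns) are treated as holes - perforations
#' yield either no transition at all or a spurious deep one where the scan
#' line exits a slanted channel, and trabecular voids deep in bone must not
#' masquerade as the tidemark. Flagged columns are filled by
#' [interpolate_gaps()] along the lateral axis; frames with no valid column
#' are filled along the elevational axis.
#'
#' @param binvol a [binarize()]d volume.
#' @param min_run minimum run length of calcified voxels (default 2).
#' @param window_um half-width of the accepted interface window around the
#'   local median interface depth (um).
#' @param median_k window (columns, odd) of the running median defining the
#'   local interface level.
#' @param mad_k optional robust rejection: when set, the acceptance
#'   half-width additionally shrinks to `mad_k` robust standard deviations
#'   (`1.4826 * MAD`) of the detected-minus-reference residuals, floored at
#'   3 voxels. Intended for noisy volumes where slanted perforation
#'   channels produce spurious deep transitions below the true interface.
#' @return A [surface_grid()].
#' @export
extract_surface_3d_ct <- function(binvol, min_run = 2L, window_um = 500,
                                  median_k = 31L, mad_k = NULL) {
  stopifnot(inherits(binvol, "binary_volume"))
  d <- dim(binvol$mask)
  ny <- d[1L]; nx <- d[3L]
  dz <- binvol$spacing[2L]
  rows <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny))
    rows[i, ] <- first_transition_rows(binvol$mask[i, , ], min_run)
  if (all(is.na(rows))) stop("no interface found in any column")
  z <- binvol$origin[2L] + (rows - 1) * dz
  k <- min(as.integer(median_k), if (nx %% 2L) nx else nx - 1L)
  resid <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) {
    zi <- z[i, ]
    det <- !is.na(zi)
    if (!any(det)) next
    ref <- stats::runmed(interpolate_gaps(zi, !det), k)
    resid[i, ] <- ifelse(det, zi - ref, NA_real_)
  }
  win <- window_um
  if (!is.null(mad_k)) {
    s_rob <- stats::mad(resid, na.rm = TRUE)
    win <- min(window_um, max(mad_k * s_rob, 3 * dz))
  }
  ok <- !is.na(resid) & abs(resid) <= win
  heights <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) {
    if (any(ok[i, ])) heights[i, ] <- interpolate_gaps(z[i, ], !ok[i, ])
  }
  empty <- is.na(heights[, 1L])
  if (any(empty)) {                      # whole frames without valid columns
    for (j in seq_len(nx))
      heights[, j] <- interpolate_gaps(heights[, j], empty)
  }
  surface_grid(heights, spacing = binvol$spacing[c(1L, 3L)], valid = ok,
               origin = c(binvol$origin[1L], binvol$origin[3L]))
}
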