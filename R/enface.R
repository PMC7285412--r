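#' Flatten a volume relative to an extracted surface
#'
#' Resamples every lateral column along depth (1D linear interpolation) so
#' that the tidemark surface sits at a common depth index: output depth row
#' `k` holds the intensity at physical depth `z(i,j) + (k - 1 - n_above) * dz`.
#' Depths falling outside the recorded data are filled with 0 and flagged in
#' the `"fill_mask"` attribute so averaging projections can exclude them.
#'
#' @param vol a [volume3d()].
#' @param surface a [surface_grid()] on the same lateral grid as `vol`.
#' @param n_above number of output rows kept above the surface.
#' @return A [volume3d()] with the surface at depth row `n_above + 1`.
#' @export
flatten_volume <- function(vol, surface, n_above = 0L) {
  stopifnot(inherits(vol, "volume3d"), inherits(surface, "surface_grid"))
  if (!identical(dim(surface$heights), dim(vol$intensities)[c(1L, 3L)]))
    stop("surface grid does not match the volume's lateral grid")
  nz <- n_depth(vol)
  dz <- vol$spacing[2L]
  zs <- surface$heights
  if (min(zs) < vol$origin[2L] - dz ||
      max(zs) > vol$origin[2L] + (nz - 1) * dz + dz)
    stop("surface lies outside the volume depth range")
  rows0 <- depth_to_row(vol, zs)            # fractional row of the surface
  ny <- n_frames(vol); nx <- n_lateral(vol)
  out <- array(0, dim = c(ny, nz, nx))
  fill <- array(FALSE, dim = c(ny, nz, nx))
  ii <- rep(seq_len(ny), times = nx)
  jj <- rep(seq_len(nx), each = ny)
  for (k in seq_len(nz)) {
    r <- rows0 + (k - 1L - n_above)
    f <- floor(r)
    w <- as.vector(r - f)
    f <- as.vector(f)
    inside <- f >= 1L & f + 1L <= nz
    exact <- f >= 1L & f <= nz & w == 0
    ok <- inside | exact
    fk <- pmin(pmax(f, 1L), nz)
    v <- (1 - w) * vol$intensities[cbind(ii, fk, jj)] +
      w * vol$intensities[cbind(ii, pmin(fk + 1L, nz), jj)]
    v[!ok] <- 0
    out[, k, ] <- v
    fill[, k, ] <- !ok
  }
  res <- volume3d(out, vol$spacing, c(vol$origin[1L], 0, vol$origin[3L]))
  attr(res, "fill_mask") <- fill
  attr(res, "n_above") <- n_above
  res
}

#' En face projection of an interface slab
#'
#' Projects a flattened volume over the slab `[offset, offset + thickness)`
#' measured downward from the tidemark, by maximum intensity (MIP) or
#' average intensity (AIP). AIP excludes fill voxels introduced by
#' flattening from the mean.
#'
#' @param flat a [flatten_volume()] output.
#' @param mode `"mip"` or `"aip"`.
#' @param thickness_um slab thickness (um); at least one voxel.
#' @param offset_um slab start depth relative to the surface (um).
#' @return An object of class `en_face_image`: `image` (frames x columns
#'   matrix), `mode`, `thickness_um`, `offset_um`, `spacing`.
#' @export
project_enface <- function(flat, mode = c("mip", "aip"), thickness_um,
                           offset_um = 0) {
  stopifnot(inherits(flat, "volume3d"))
  mode <- match.arg(mode)
  dz <- flat$spacing[2L]
  n_above <- attr(flat, "n_above") %||% 0L
  if (thickness_um < dz) stop("slab thinner than one voxel")
  k0 <- n_above + 1L + as.integer(floor(offset_um / dz))
  nk <- max(1L, as.integer(round(thickness_um / dz)))
  ks <- k0:(k0 + nk - 1L)
  ks <- ks[ks >= 1L & ks <= n_depth(flat)]
  if (length(ks) == 0L) stop("slab lies entirely outside the volume")
  sub <- flat$intensities[, ks, , drop = FALSE]
  if (mode == "mip") {
    img <- apply(sub, c(1L, 3L), max)
  } else {
    fm <- attr(flat, "fill_mask")
    if (is.null(fm)) {
      img <- apply(sub, c(1L, 3L), mean)
    } else {
      good <- !fm[, ks, , drop = FALSE]
      cnt <- apply(good, c(1L, 3L), sum)
      tot <- apply(sub * good, c(1L, 3L), sum)
      img <- ifelse(cnt > 0, tot / pmax(cnt, 1L), 0)
    }
  }
  structure(list(image = img, mode = mode, thickness_um = thickness_um,
                 offset_um = offset_um,
                 spacing = flat$spacing[c(1L, 3L)]),
            class = "en_face_image")
}

#' @export
print.en_face_image <- function(x, ...) {
  cat(sprintf("<en_face_image> %s, slab %g um at offset %g um, %d x %d px\n",
              toupper(x$mode), x$thickness_um, x$offset_um,
              nrow(x$image), ncol(x$image)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
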