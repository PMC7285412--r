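#' Parameters of the synthetic paired-volume generator
#'
#' Defaults reproduce the acquisition geometry of the study conditions:
#' a 7 x 7 mm scanned field, B-scan pixels of 15 x 15 um with a 32 um
#' elevational step (220 frames over 7 mm), and an isotropic 21 um micro-CT
#' voxel. The micro-CT field extends `ct_margin_mm` beyond the ultrasound
#' field on every side, as the real micro-CT scans the whole disk.
#'
#' The ground-truth tidemark surface is a tilted plane plus a low-frequency
#' waviness component plus a band-limited high-frequency roughness component,
#' each a finite sum of random-phase cosines so the surface is analytic and
#' can be sampled exactly on both modality grids. `waviness_amplitude` and
#' `roughness_amplitude` are the RMS amplitudes (um) of the two components.
#'
#' @param field_size_mm side length of the square US field (mm).
#' @param ct_margin_mm extra micro-CT field margin on each side (mm).
#' @param depth_mm imaged depth (mm).
#' @param us_spacing US voxel spacing `(axial, lateral, elevational)` um.
#' @param ct_spacing isotropic micro-CT voxel size (um).
#' @param surface_depth_um mean tidemark depth (um).
#' @param plane_slope_deg slope of the tilted-plane component (degrees).
#' @param waviness_amplitude RMS of the waviness component (um).
#' @param waviness_wavelength_um range of waviness wavelengths (um);
#'   `NULL` means `c(1.15, 2) * field size`, i.e. undulation at the scale of
#'   the whole specimen.
#' @param roughness_amplitude RMS of the roughness component (um).
#' @param roughness_correlation_length characteristic lateral scale of the
#'   roughness (um); wavelengths are drawn from 1-3 times this length.
#' @param cartilage_offset_um depth of the tidemark below the cartilage
#'   surface echo (um).
#' @param band_sigma_um axial Gaussian sigma of the echo bands (um);
#'   default emulates the ~40 um axial resolution of a 25 MHz transducer.
#' @param noise_floor upper bound of the additive background noise
#'   (grayscale units); saline voxels never exceed it.
#' @param echo_cartilage,echo_tidemark peak echo amplitudes of the two
#'   bright bands (grayscale units).
#' @param speckle multiplicative speckle contrast on the echo bands in
#'   `[0, 1]`; `0` disables speckle, `1` is fully developed Rayleigh speckle.
#' @param ct_bone_level,ct_background micro-CT intensities of calcified
#'   tissue and of soft tissue/saline.
#' @param ct_noise_sd additive Gaussian noise SD on the micro-CT volume.
#' @param crack_fraction fraction of US columns with suppressed tidemark echo.
#' @param hole_fraction fraction of micro-CT columns inside perforations.
#' @param hole_radius_um radius of a cylindrical perforation (um).
#' @param tilt_deg small global in-plane tilt of the micro-CT volume (deg).
#' @param max_rot_deg,max_trans_um bounds of the random true rigid transform
#'   between the CT and US frames.
#' @param approx_error_um amplitude of the smooth perturbation added to the
#'   true surface to emulate the manually drawn approximate profile (um);
#'   must stay below half the first-peak search window (~150 um).
#' @param seed integer seed that fully determines all stochastic draws.
#' @return A validated list of class `synth_params`.
#' @export
synth_params <- function(field_size_mm = 7,
                         ct_margin_mm = 1.2,
                         depth_mm = 2.8,
                         us_spacing = c(axial = 15, lateral = 15, elevational = 32),
                         ct_spacing = 21,
                         surface_depth_um = 1650,
                         plane_slope_deg = 0.5,
                         waviness_amplitude = 100,
                         waviness_wavelength_um = NULL,
                         roughness_amplitude = 30,
                         roughness_correlation_length = 150,
                         cartilage_offset_um = 700,
                         band_sigma_um = 17,
                         noise_floor = 8,
                         echo_cartilage = 120,
                         echo_tidemark = 200,
                         speckle = 0.5,
                         ct_bone_level = 180,
                         ct_background = 20,
                         ct_noise_sd = 10,
                         crack_fraction = 0.03,
                         hole_fraction = 0.03,
                         hole_radius_um = 60,
                         tilt_deg = 1.5,
                         max_rot_deg = 3,
                         max_trans_um = 800,
                         approx_error_um = 80,
                         seed = 1L) {
  p <- as.list(environment())
  if (is.null(p$waviness_wavelength_um))
    p$waviness_wavelength_um <- c(1.15, 2) * field_size_mm * 1000
  stopifnot(all(p$us_spacing > 0), p$ct_spacing > 0, p$field_size_mm > 0,
            p$depth_mm > 0, p$waviness_amplitude >= 0,
            p$roughness_amplitude >= 0, p$roughness_correlation_length > 0,
            p$crack_fraction >= 0, p$crack_fraction < 0.2,
            p$hole_fraction >= 0, p$hole_fraction < 0.2,
            p$speckle >= 0, p$speckle <= 1,
            p$noise_floor >= 0, p$approx_error_um >= 0, p$approx_error_um <= 140,
            abs(p$tilt_deg) < 10, p$max_rot_deg >= 0, p$max_trans_um >= 0)
  names(p$us_spacing) <- c("axial", "lateral", "elevational")
  p$seed <- as.integer(p$seed)
  class(p) <- "synth_params"
  p
}

## --- analytic ground-truth surface --------------------------------------

## n grid nodes along an axis of physical length len at spacing h
grid_n <- function(len_um, h_um) as.integer(round(len_um / h_um)) + 1L

## evaluate the cosine-sum surface at arbitrary (x, y) um
eval_surface_fun <- function(fun, x, y) {
  z <- fun$z0 + fun$gx * (x - fun$cx) + fun$gy * (y - fun$cy)
  tt <- fun$terms
  if (nrow(tt)) {
    for (k in seq_len(nrow(tt)))
      z <- z + tt$amp[k] * cos(2 * pi * (tt$fx[k] * x + tt$fy[k] * y) + tt$phase[k])
  }
  z
}

## cosine terms with total RMS `rms`, wavelengths drawn from `wl_range`
draw_cosine_terms <- function(n_terms, rms, wl_range, component) {
  if (rms <= 0 || n_terms == 0L)
    return(data.frame(amp = numeric(0), fx = numeric(0), fy = numeric(0),
                      phase = numeric(0), component = character(0)))
  wl <- runif(n_terms, wl_range[1], wl_range[2])
  th <- runif(n_terms, 0, 2 * pi)
  a <- runif(n_terms, 0.5, 1)
  a <- a * rms / sqrt(sum(a^2) / 2)        # RMS of sum of cosines = sqrt(sum a^2 / 2)
  data.frame(amp = a, fx = cos(th) / wl, fy = sin(th) / wl,
             phase = runif(n_terms, 0, 2 * pi), component = component)
}

#' Generate the ground truth of one synthetic osteochondral disk
#'
#' Draws the true tidemark surface (plane + waviness + roughness), the crack
#' mask on the US lateral grid, the perforation (hole) mask on the CT lateral
#' grid, the true CT-to-US rigid transform, and the CT tilt. Everything is a
#' deterministic function of `params$seed`.
#'
#' @param params a [synth_params()] object.
#' @return An object of class `tidemark_ground_truth` with fields
#'   `surface_fun` (analytic surface description), `true_transform`
#'   (CT frame -> US frame), `crack_mask`, `hole_mask`, `tilt_deg`, `params`,
#'   `seed`.
#' @export
generate_ground_truth <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  set.seed(p$seed)
  field <- p$field_size_mm * 1000
  depth <- p$depth_mm * 1000

  az <- runif(1, 0, 2 * pi)                # direction of the plane tilt
  g <- tan(p$plane_slope_deg * pi / 180)
  fun <- list(z0 = p$surface_depth_um, gx = g * cos(az), gy = g * sin(az),
              cx = field / 2, cy = field / 2,
              terms = rbind(
                draw_cosine_terms(6L, p$waviness_amplitude,
                                  p$waviness_wavelength_um, "waviness"),
                draw_cosine_terms(40L, p$roughness_amplitude,
                                  p$roughness_correlation_length * c(1, 3),
                                  "roughness")))

  ## realized excursion must stay inside the imaged depth
  nx <- grid_n(field, p$us_spacing[["lateral"]])
  ny <- grid_n(field, p$us_spacing[["elevational"]])
  xs <- (seq_len(nx) - 1) * p$us_spacing[["lateral"]]
  ys <- (seq_len(ny) - 1) * p$us_spacing[["elevational"]]
  zs <- outer(ys, xs, function(y, x) eval_surface_fun(fun, x, y))
  guard <- 4 * p$band_sigma_um + p$approx_error_um
  if (min(zs) - p$cartilage_offset_um - guard - 100 < 0 ||
      max(zs) + guard > depth - 50)
    stop("surface amplitudes exceed the imaged depth range; ",
         "reduce amplitudes or increase depth_mm")

  crack_mask <- matrix(FALSE, ny, nx)
  if (p$crack_fraction > 0) {
    n_target <- p$crack_fraction * ny * nx
    while (sum(crack_mask) < n_target) {
      i <- sample.int(ny, 1L)
      j0 <- sample.int(nx, 1L)
      len <- sample(3:10, 1L)
      crack_mask[i, j0:min(nx, j0 + len - 1L)] <- TRUE
    }
  }

  margin <- p$ct_margin_mm * 1000
  extent <- field + 2 * margin
  nct <- grid_n(extent, p$ct_spacing)
  xc <- -margin + (seq_len(nct) - 1) * p$ct_spacing
  hole_mask <- matrix(FALSE, nct, nct)
  hole_centers <- cbind(x = numeric(0), y = numeric(0))
  if (p$hole_fraction > 0) {
    vox_per_hole <- pi * p$hole_radius_um^2 / p$ct_spacing^2
    n_holes <- max(1L, round(p$hole_fraction * nct * nct / vox_per_hole))
    hx <- runif(n_holes, 0, field)         # keep holes inside the US overlap
    hy <- runif(n_holes, 0, field)
    hole_centers <- cbind(x = hx, y = hy)
    for (h in seq_len(n_holes)) {
      dj <- which(abs(xc - hx[h]) <= p$hole_radius_um)
      di <- which(abs(xc - hy[h]) <= p$hole_radius_um)
      if (length(di) && length(dj)) {
        sub <- outer((xc[di] - hy[h])^2, (xc[dj] - hx[h])^2, "+") <= p$hole_radius_um^2
        hole_mask[di, dj] <- hole_mask[di, dj] | sub
      }
    }
  }
  stopifnot(mean(crack_mask) < 0.2, mean(hole_mask) < 0.2)

  tr <- random_rigid_transform(p$max_rot_deg, p$max_trans_um)
  structure(list(surface_fun = fun, true_transform = tr,
                 crack_mask = crack_mask, hole_mask = hole_mask,
                 hole_centers = hole_centers,
                 tilt_deg = p$tilt_deg, params = p, seed = p$seed),
            class = "tidemark_ground_truth")
}

#' Sample the true surface on the US lateral grid
#'
#' @param gt a [generate_ground_truth()] object.
#' @param components keep the generating plane/waviness/roughness fields as
#'   the `"components"` attribute?
#' @return A [surface_grid()] in the US frame.
#' @export
true_surface_us_grid <- function(gt, components = FALSE) {
  p <- gt$params
  field <- p$field_size_mm * 1000
  dx <- p$us_spacing[["lateral"]]; dy <- p$us_spacing[["elevational"]]
  xs <- (seq_len(grid_n(field, dx)) - 1) * dx
  ys <- (seq_len(grid_n(field, dy)) - 1) * dy
  fun <- gt$surface_fun
  comp_field <- function(f) outer(ys, xs, function(y, x) eval_surface_fun(f, x, y))
  h <- comp_field(fun)
  s <- surface_grid(h, spacing = c(dy, dx), valid = !gt$crack_mask)
  if (components) {
    base <- fun; base$terms <- fun$terms[0, ]
    fw <- base; fw$z0 <- 0; fw$gx <- 0; fw$gy <- 0
    fw$terms <- fun$terms[fun$terms$component == "waviness", ]
    fr <- fw; fr$terms <- fun$terms[fun$terms$component == "roughness", ]
    attr(s, "components") <- list(plane = comp_field(base),
                                  waviness = comp_field(fw),
                                  roughness = comp_field(fr))
  }
  s
}

#' Generate a ground-truth tidemark surface
#'
#' Convenience wrapper: draws a ground truth from `params` and returns the
#' true surface sampled on the US grid, with the generating plane, waviness
#' and roughness fields retained in the `"components"` attribute and the full
#' ground truth in the `"ground_truth"` attribute.
#'
#' @inheritParams generate_ground_truth
#' @return A [surface_grid()].
#' @export
generate_ground_truth_surface <- function(params = synth_params()) {
  gt <- generate_ground_truth(params)
  s <- true_surface_us_grid(gt, components = TRUE)
  attr(s, "ground_truth") <- gt
  s
}

## --- ultrasound volume ----------------------------------------------------

#' Simulate the B-scan stack of a synthetic disk
#'
#' Builds the US volume: a dark saline region (uniform noise bounded by
#' `noise_floor`), a bright cartilage-surface echo band, a brighter tidemark
#' band centred on the true surface with a Gaussian axial profile emulating
#' the ~40 um axial resolution, multiplicative Rayleigh speckle on the bands,
#' and suppressed tidemark echo in crack columns. Also returns the surrogate
#' "manually drawn" approximate profile: the true surface plus a smooth
#' perturbation bounded by `approx_error_um`.
#'
#' @param gt a [generate_ground_truth()] object.
#' @param params generator parameters; defaults to `gt$params`.
#' @return A list with elements `volume` (a [volume3d()]) and
#'   `approx` (matrix of approximate tidemark depths, um, frames x columns).
#' @export
simulate_us_volume <- function(gt, params = gt$params) {
  stopifnot(inherits(gt, "tidemark_ground_truth"))
  p <- params
  set.seed(p$seed + 1L)
  field <- p$field_size_mm * 1000
  dz <- p$us_spacing[["axial"]]; dx <- p$us_spacing[["lateral"]]
  dy <- p$us_spacing[["elevational"]]
  nz <- grid_n(p$depth_mm * 1000, dz)
  s <- true_surface_us_grid(gt)
  zs <- s$heights
  ny <- nrow(zs); nx <- ncol(zs)
  zc <- zs - p$cartilage_offset_um
  tide_amp <- ifelse(gt$crack_mask, 0, p$echo_tidemark)
  z <- (seq_len(nz) - 1) * dz
  sg2 <- 2 * p$band_sigma_um^2
  ray_mean <- sqrt(pi / 2)

  vol <- array(0, dim = c(ny, nz, nx))
  for (k in seq_len(nz)) {
    band <- p$echo_cartilage * exp(-(z[k] - zc)^2 / sg2) +
      tide_amp * exp(-(z[k] - zs)^2 / sg2)
    if (p$speckle > 0) {
      ray <- sqrt(-2 * log(matrix(runif(ny * nx), ny, nx))) / ray_mean
      band <- band * ((1 - p$speckle) + p$speckle * ray)
    }
    base <- if (p$noise_floor > 0)
      matrix(runif(ny * nx, 0, p$noise_floor), ny, nx) else 0
    vol[, k, ] <- base + band
  }

  ## surrogate manual profile: smooth in-frame perturbation of the truth
  amp <- runif(ny, 0.4, 1) * p$approx_error_um
  ph <- runif(ny, 0, 2 * pi)
  wl <- runif(ny, 0.5, 1) * max(field, 1)
  xs <- (seq_len(nx) - 1) * dx
  pert <- t(vapply(seq_len(ny),
                   function(i) amp[i] * cos(2 * pi * xs / wl[i] + ph[i]),
                   numeric(nx)))
  list(volume = volume3d(vol, spacing = c(dy, dz, dx)),
       approx = zs + pert)
}

## --- micro-CT volume -------------------------------------------------------

## true surface depth on the CT lateral grid, in the (tilted) CT frame:
## solve (R p + t)_z = z_us((R p + t)_x, (R p + t)_y) for z by fixed point,
## then add the in-plane tilt slope about the frame centre.
ct_true_surface <- function(gt, with_tilt = TRUE) {
  p <- gt$params
  margin <- p$ct_margin_mm * 1000
  extent <- p$field_size_mm * 1000 + 2 * margin
  n <- grid_n(extent, p$ct_spacing)
  xc <- -margin + (seq_len(n) - 1) * p$ct_spacing
  X <- matrix(xc, n, n, byrow = TRUE)     # lateral x per (frame row i, col j)
  Y <- matrix(xc, n, n)                   # elevational y
  R <- gt$true_transform$R; tr <- gt$true_transform$t
  f <- gt$surface_fun
  Z <- matrix(f$z0, n, n)
  for (it in 1:8) {
    xu <- R[1, 1] * X + R[1, 2] * Y + R[1, 3] * Z + tr[1]
    yu <- R[2, 1] * X + R[2, 2] * Y + R[2, 3] * Z + tr[2]
    Z <- (eval_surface_fun(f, xu, yu) - R[3, 1] * X - R[3, 2] * Y - tr[3]) / R[3, 3]
  }
  if (with_tilt && gt$tilt_deg != 0) {
    cx <- (xc[1] + xc[n]) / 2
    Z <- Z + tan(gt$tilt_deg * pi / 180) * (X - cx)
  }
  surface_grid(Z, spacing = c(p$ct_spacing, p$ct_spacing),
               valid = !gt$hole_mask, origin = c(-margin, -margin))
}

#' Simulate the micro-CT volume of a synthetic disk
#'
#' High-intensity calcified tissue below the true surface (expressed in the
#' CT frame through the true rigid transform and the global tilt),
#' low-intensity soft tissue above, additive Gaussian noise, and zero-intensity
#' cylindrical perforation channels through the interface at hole columns.
#' Channels run along the normal of the specimen's mean surface plane (as
#' anatomical perforations traverse the calcified plate), not along the CT
#' depth axis. The intensity ramps linearly across one voxel at the
#' interface to emulate partial-volume averaging.
#'
#' @inheritParams simulate_us_volume
#' @return A [volume3d()] in the (tilted) CT frame, with the true CT-frame
#'   surface attached as attribute `"ct_surface"`.
#' @export
simulate_ct_volume <- function(gt, params = gt$params) {
  stopifnot(inherits(gt, "tidemark_ground_truth"))
  p <- params
  set.seed(p$seed + 2L)
  h <- p$ct_spacing
  surf <- ct_true_surface(gt, with_tilt = TRUE)
  zs <- surf$heights
  n <- nrow(zs)
  nz <- grid_n(p$depth_mm * 1000, h)
  z <- (seq_len(nz) - 1) * h
  lvl <- p$ct_bone_level - p$ct_background

  ## mean surface plane; channels run along its normal
  xc <- surf$origin[2L] + (seq_len(n) - 1) * h
  yc <- surf$origin[1L] + (seq_len(n) - 1) * h
  pl <- coef(lsfit(cbind(rep(xc, each = n), rep(yc, times = n)), as.vector(zs)))
  sx <- pl[[2L]]; sy <- pl[[3L]]
  hc <- gt$hole_centers
  zh <- if (nrow(hc)) zs[cbind(pmin(pmax(round((hc[, "y"] - yc[1]) / h) + 1, 1), n),
                               pmin(pmax(round((hc[, "x"] - xc[1]) / h) + 1, 1), n))]

  vol <- array(0, dim = c(n, nz, n))
  r <- p$hole_radius_um
  for (k in seq_len(nz)) {
    frac <- pmin(pmax((z[k] - zs) / h + 0.5, 0), 1)   # keeps matrix dims
    slice <- p$ct_background + lvl * frac
    if (p$ct_noise_sd > 0)
      slice <- slice + matrix(rnorm(n * n, 0, p$ct_noise_sd), n, n)
    for (q in seq_len(nrow(hc))) {
      cx0 <- hc[q, "x"] + sx * (z[k] - zh[q])     # channel axis at this depth
      cy0 <- hc[q, "y"] + sy * (z[k] - zh[q])
      dj <- which(abs(xc - cx0) <= r)
      di <- which(abs(yc - cy0) <= r)
      if (length(di) && length(dj)) {
        inside <- outer((yc[di] - cy0)^2, (xc[dj] - cx0)^2, "+") <= r^2
        open <- z[k] >= zh[q] - 150                # channel starts above plate
        if (open) {
          blk <- slice[di, dj, drop = FALSE]
          blk[inside] <- 0
          slice[di, dj] <- blk
        }
      }
    }
    vol[, k, ] <- slice
  }
  out <- volume3d(vol, spacing = c(h, h, h),
                  origin = c(surf$origin[1], 0, surf$origin[2]))
  attr(out, "ct_surface") <- surf
  out
}
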