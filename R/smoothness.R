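#' Fit a polynomial reference surface to a heightmap
#'
#' Ordinary least squares fit of a bivariate polynomial to the surface
#' heights over the lateral grid. `order = 1` fits the plane
#' `{1, x, y}` (accounting for tilts in x and y, the waviness reference);
#' `order = 5` fits all 21 monomials `x^a y^b` with `a + b <= 5` (the
#' roughness reference, which absorbs the waviness). Lateral coordinates are
#' centred and scaled to `[-1, 1]` for conditioning; fitted heights are
#' returned on the original grid.
#'
#' @param s a [surface_grid()].
#' @param order polynomial order, 1 or 5.
#' @param use_mask exclude interpolated (invalid) nodes from the fit?
#'   Default `FALSE`: the surface is interpolated first, then indices are
#'   computed on the full grid.
#' @return An object of class `reference_surface_fit` with fields `order`,
#'   `coefficients`, `fitted` (matrix on the input grid), `powers`.
#' @export
fit_reference_surface <- function(s, order = c(1L, 5L), use_mask = FALSE) {
  stopifnot(inherits(s, "surface_grid"))
  order <- as.integer(order[1L])
  if (!order %in% c(1L, 5L)) stop("order must be 1 or 5")
  m <- nrow(s$heights); n <- ncol(s$heights)
  powers <- if (order == 1L) cbind(a = c(0L, 1L, 0L), b = c(0L, 0L, 1L))
  else {
    pw <- expand.grid(a = 0:5, b = 0:5)
    as.matrix(pw[pw$a + pw$b <= 5L, c("a", "b")])
  }
  if (m * n < nrow(powers)) stop("not enough grid nodes for the basis")
  sc <- function(v) if (max(v) > min(v)) 2 * (v - mean(range(v))) / diff(range(v)) else v - mean(v)
  u <- sc(surface_x(s))                     # lateral, per column
  v <- sc(surface_y(s))                     # elevational, per row
  U <- rep(u, each = m); V <- rep(v, times = n)
  X <- vapply(seq_len(nrow(powers)),
              function(k) U^powers[k, 1L] * V^powers[k, 2L],
              numeric(m * n))
  w <- if (use_mask) as.vector(s$valid) else rep(TRUE, m * n)
  qr_fit <- qr(X[w, , drop = FALSE])
  if (qr_fit$rank < ncol(X)) stop("rank-deficient polynomial design")
  beta <- qr.coef(qr_fit, as.vector(s$heights)[w])
  fitted <- matrix(X %*% beta, m, n)
  structure(list(order = order, coefficients = beta, fitted = fitted,
                 powers = powers), class = "reference_surface_fit")
}

check_shapes <- function(s, ref) {
  stopifnot(inherits(s, "surface_grid"), inherits(ref, "reference_surface_fit"))
  if (!identical(dim(s$heights), dim(ref$fitted)))
    stop("surface and reference fit have different shapes")
}

#' Areal mean-absolute deviation index Sa
#'
#' `Sa = (1 / MN) * sum_ij |s(i,j) - SR(i,j)|`, the mean absolute deviation
#' of the surface from its polynomial reference.
#'
#' @param s a [surface_grid()].
#' @param ref a [fit_reference_surface()] on the same grid.
#' @return Sa in micrometres.
#' @export
sa_index <- function(s, ref) {
  check_shapes(s, ref)
  mean(abs(s$heights - ref$fitted))
}

#' Areal root-mean-square deviation index Sq
#'
#' `Sq = sqrt((1 / MN) * sum_ij (s(i,j) - SR(i,j))^2)`, the RMS deviation of
#' the surface from its polynomial reference.
#'
#' @inheritParams sa_index
#' @return Sq in micrometres.
#' @export
sq_index <- function(s, ref) {
  check_shapes(s, ref)
  sqrt(mean((s$heights - ref$fitted)^2))
}

#' Waviness and roughness panel of a tidemark surface
#'
#' Computes the four smoothness indices of a surface: waviness `SWa`/`SWq`
#' (Sa/Sq against the first-order plane reference, macroscopic smoothness)
#' and roughness `SRa`/`SRq` (Sa/Sq against the fifth-order polynomial
#' reference, microscopic smoothness).
#'
#' @param s a [surface_grid()].
#' @param use_mask passed to [fit_reference_surface()].
#' @return A one-row `data.frame` with columns `SWa`, `SWq`, `SRa`, `SRq`
#'   (um).
#' @export
smoothness_panel <- function(s, use_mask = FALSE) {
  w <- fit_reference_surface(s, 1L, use_mask = use_mask)
  r <- fit_reference_surface(s, 5L, use_mask = use_mask)
  data.frame(SWa = sa_index(s, w), SWq = sq_index(s, w),
             SRa = sa_index(s, r), SRq = sq_index(s, r))
}

#' Pearson correlation report
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution with `n - 2` degrees of freedom; `p < 0.05` is the
#' conventional significance level for a correlation.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return A list with `r`, `p`, `n`.
#' @export
pearson_report <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
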