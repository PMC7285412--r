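#' Rigid transform in 3D
#'
#' A rotation plus translation, `p' = R p + t`, with all lengths in
#' micrometres. `R` must be a proper rotation (orthonormal, det +1).
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (um).
#' @param tol tolerance for the orthonormality / determinant check.
#' @return An object of class `rigid_transform` with fields `R` and `t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0), tol = 1e-8) {
  R <- unname(as.matrix(R))
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L,
            all(is.finite(R)), all(is.finite(t)))
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("R is not orthonormal (R'R != I)")
  if (abs(det(R) - 1) > tol)
    stop("R is not a proper rotation (det != +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  rotation", sprintf("%.4f deg", rotation_angle_deg(x)),
      " translation (um):", sprintf("%.2f", x$t), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix of points (um).
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) {
  points <- as_points(points)
  sweep(points %*% t(transform$R), 2L, transform$t, "+")
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$t))
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; `axis` need not be normalized.
#'
#' @param axis length-3 rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis)
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rigid transform
#' @param transform a `rigid_transform` (or a 3x3 rotation matrix).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$R else transform
  c <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c))) * 180 / pi
}

#' Draw a random small rigid transform
#'
#' Rotation about a uniformly random axis by an angle uniform on
#' `[0, max_rot_deg]`, and a translation uniform componentwise on
#' `[-max_trans_um, max_trans_um]`. Uses the current RNG state.
#'
#' @param max_rot_deg maximum rotation angle (degrees).
#' @param max_trans_um maximum translation per axis (um).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_rot_deg = 3, max_trans_um = 800) {
  ax <- rnorm(3)
  ang <- runif(1, 0, max_rot_deg)
  tr <- runif(3, -max_trans_um, max_trans_um)
  rigid_transform(rotation_about_axis(ax, ang), tr)
}

identity_transform <- function() rigid_transform()

as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  stopifnot(ncol(points) == 3L)
  storage.mode(points) <- "double"
  unname(points)
}
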