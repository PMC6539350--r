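#' Elastica parameter set for one leaflet
#'
#' Bundles the geometric and elastic constants of a single leaflet together
#' with the two Lagrangian angles that determine its deformed shape: the
#' free-edge tangent angle `theta_l` (with respect to the annular axis) and
#' the end-load inclination `alpha` (with respect to the apical axis).  In
#' the leaflet frame the chordal pull acts along `(-sin(alpha), cos(alpha))`,
#' i.e. `alpha > 0` tilts the load away from the opposite leaflet.
#'
#' @param l Leaflet length in mm.
#' @param B Bending stiffness in mN mm^2.
#' @param theta_l Free-edge tangent angle in radians, in (-pi/2, pi/2).
#' @param alpha Load inclination in radians, in (-pi/2, pi/2).
#' @return An object of class `elastica_params`.
#' @export
elastica_params <- function(l, B, theta_l, alpha) {
  stopifnot(is.numeric(l), length(l) == 1L, l > 0,
            is.numeric(B), length(B) == 1L, B > 0,
            is.numeric(theta_l), length(theta_l) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (abs(theta_l) >= pi / 2)
    stop("theta_l must lie in (-pi/2, pi/2)", call. = FALSE)
  if (abs(alpha) >= pi / 2)
    stop("alpha must lie in (-pi/2, pi/2)", call. = FALSE)
  structure(list(l = l, B = B, theta_l = theta_l, alpha = alpha),
            class = "elastica_params")
}

#' Elliptic eccentricity from the end angles
#'
#' `2 k^2 = 1 + sin(theta_l - alpha)`.
#'
#' @param theta_l Free-edge tangent angle (rad).
#' @param alpha Load inclination (rad).
#' @return Eccentricity `k` in (0, 1].
#' @export
eccentricity_from_angles <- function(theta_l, alpha) {
  k2 <- (1 + sin(theta_l - alpha)) / 2
  if (any(k2 <= 0) || any(k2 > 1))
    stop("degenerate (theta_l, alpha): eccentricity outside (0, 1]",
         call. = FALSE)
  sqrt(k2)
}

#' Reference amplitude of the elastica solution
#'
#' `2 k^2 sin^2(phi_alpha) = 1 - sin(alpha)`; `phi_alpha` is the Jacobi
#' amplitude at the clamped root (where the tangent angle is zero).
#'
#' @param k Eccentricity.
#' @param alpha Load inclination (rad).
#' @return `phi_alpha` in `[0, pi/2]`.
#' @export
reference_amplitude <- function(k, alpha) {
  arg <- (1 - sin(alpha)) / (2 * k^2)
  if (any(arg < 0) || any(arg > 1 + 1e-12))
    stop("incompatible (k, alpha): amplitude argument outside [0, 1]",
         call. = FALSE)
  asin(sqrt(pmin(arg, 1)))
}

#' Dimensionless load frequency
#'
#' `omega = K[k] - F[phi_alpha, k]`, so that the end load is
#' `P = B omega^2 / l^2`.
#'
#' @param k Eccentricity.
#' @param phi_alpha Reference amplitude (rad).
#' @return `omega >= 0`.
#' @export
load_frequency <- function(k, phi_alpha) {
  as.numeric(c_ellK(k) - c_ellF(phi_alpha, k))
}

#' End-point load magnitude
#'
#' @param params An [elastica_params()] object.
#' @return Load `P` in mN.
#' @export
tip_load <- function(params) {
  stopifnot(inherits(params, "elastica_params"))
  k <- eccentricity_from_angles(params$theta_l, params$alpha)
  phia <- reference_amplitude(k, params$alpha)
  om <- load_frequency(k, phia)
  params$B * om^2 / params$l^2
}

#' Jacobi amplitude along the elastica
#'
#' `phi(s) = am[omega s + F(phi_alpha, k), k]`; `phi(0) = phi_alpha` and
#' `phi(1) = pi/2` at the free edge.
#'
#' @param s Curvilinear abscissa(e) in `[0, 1]`.
#' @param omega Load frequency.
#' @param phi_alpha Reference amplitude (rad).
#' @param k Eccentricity.
#' @return Amplitude(s) `phi(s)` in radians.
#' @export
amplitude_at <- function(s, omega, phi_alpha, k) {
  stopifnot(all(s >= 0), all(s <= 1))
  as.numeric(c_am(omega * s + as.numeric(c_ellF(phi_alpha, k)), k))
}

#' Solve the elastica for one leaflet
#'
#' Closed-form solution of the inextensible cantilever under a tensile
#' end-point load inclined by `alpha` from the apical axis.  The clamped
#' root sits at the origin with a horizontal tangent; `y` grows toward the
#' apex.  The unloaded case `theta_l == alpha` returns the straight
#' horizontal beam.
#'
#' @inheritParams elastica_params
#' @return An object of class `elastica_solution` with fields `params`,
#'   `k`, `phi_alpha`, `omega`, `P` (mN), `tip` (named vector, mm) and
#'   `root_moment` (mN mm).
#' @examples
#' sol <- solve_elastica(theta_l = 45 * pi / 180, alpha = 10 * pi / 180,
#'                       l = 18, B = 500)
#' sol$tip
#' @export
solve_elastica <- function(theta_l, alpha, l, B) {
  params <- elastica_params(l, B, theta_l, alpha)
  core <- c_elastica_core(theta_l, alpha)
  if (core[["ok"]] != 1)
    stop("invalid (theta_l, alpha) pair for a tensile elastica", call. = FALSE)
  P <- B * core[["omega"]]^2 / l^2
  structure(list(
    params = params,
    k = core[["k"]],
    phi_alpha = core[["phi_alpha"]],
    omega = core[["omega"]],
    P = P,
    tip = c(x = l * core[["x_tip"]], y = l * core[["y_tip"]]),
    root_moment = B * core[["kappa0"]] / l
  ), class = "elastica_solution")
}

#' Deformed leaflet shape
#'
#' Evaluates the parametric closed-form shape at curvilinear abscissae
#' `s in [0, 1]` (arclength scaled by the leaflet length).
#'
#' @param solution An `elastica_solution`.
#' @param s Abscissae in `[0, 1]`.
#' @return A data frame with columns `s`, `x_mm`, `y_mm`, `theta`.
#' @export
elastica_shape <- function(solution, s = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(solution, "elastica_solution"),
            all(s >= 0), all(s <= 1))
  p <- solution$params
  m <- c_elastica_shape(s, p$theta_l, p$alpha)
  data.frame(s = s, x_mm = p$l * m[, "x"], y_mm = p$l * m[, "y"],
             theta = m[, "theta"])
}

#' Free-edge position
#'
#' @param solution An `elastica_solution`.
#' @return Named vector `c(x, y)` in mm.
#' @export
tip_position <- function(solution) {
  stopifnot(inherits(solution, "elastica_solution"))
  solution$tip
}

#' Bending moment at the clamped root
#'
#' `M = B kappa(0)` with the curvature taken from the analytic tangent-angle
#' field, `l kappa(0) = 2 k omega cos(phi_alpha)`.  Reported as a magnitude;
#' the free-edge curvature is identically zero for an end-point load.
#'
#' @param solution An `elastica_solution`.
#' @return Root moment in mN mm.
#' @export
root_moment <- function(solution) {
  stopifnot(inherits(solution, "elastica_solution"))
  solution$root_moment
}

#' @export
print.elastica_solution <- function(x, ...) {
  p <- x$params
  cat("Elastica solution\n")
  cat(sprintf("  l = %.3g mm, B = %.3g mN mm^2\n", p$l, p$B))
  cat(sprintf("  theta_l = %.2f deg, alpha = %.2f deg\n",
              p$theta_l * 180 / pi, p$alpha * 180 / pi))
  cat(sprintf("  k = %.6f, phi_alpha = %.4f rad, omega = %.6f\n",
              x$k, x$phi_alpha, x$omega))
  cat(sprintf("  P = %.4f mN, tip = (%.3f, %.3f) mm, M_root = %.3f mN mm\n",
              x$P, x$tip[["x"]], x$tip[["y"]], x$root_moment))
  invisible(x)
}

#' Export a leaflet shape as CSV
#'
#' Writes columns `s, x_mm, y_mm` for one leaflet in one configuration.
#'
#' @param solution An `elastica_solution`.
#' @param path Output file path.
#' @param n Number of sampling points along the leaflet.
#' @return The path, invisibly.
#' @export
write_shape_csv <- function(solution, path, n = 101) {
  df <- elastica_shape(solution, seq(0, 1, length.out = n))
  write.csv(df[, c("s", "x_mm", "y_mm")], path, row.names = FALSE)
  invisible(path)
}
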