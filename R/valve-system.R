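#' Clinical measurements defining a patient
#'
#' The echocardiographic and constitutive inputs of the planar valve model.
#' Defaults are the cohort means of the reference dataset.  The global frame
#' places the anterior annular hinge at the origin and the posterior hinge at
#' `(MAD_pre, 0)`, with `y` increasing toward the apex; leaflet angles are
#' accepted in degrees, annulus-to-papillary-head heights are measured from
#' the annular plane (`y = 0`) down to the papillary head.
#'
#' @param MAD_pre Preoperative mitral annular diameter, mm.
#' @param IPD_pre End-diastolic interpapillary distance, mm.
#' @param TH_pre Tenting height, mm.
#' @param TH_opt Target coaptation height, mm (must be below `TH_pre`).
#' @param delta_a,delta_p Anterior/posterior leaflet angles, degrees.
#' @param h_a,h_p Annulus-to-papillary-head heights, mm.
#' @param l_a,l_p Leaflet lengths, mm.
#' @param B Leaflet bending stiffness, mN mm^2.
#' @param material Chordal constitutive constants, a [chorda_material()].
#' @return An object of class `valve_measurements`.
#' @export
valve_measurements <- function(MAD_pre = 40, IPD_pre = 44.6, TH_pre = 12.4,
                               TH_opt = 6.8, delta_a = 32.6, delta_p = 56.8,
                               h_a = 45, h_p = 28, l_a = 18, l_p = 13,
                               B = 500, material = chorda_material()) {
  m <- list(MAD_pre = MAD_pre, IPD_pre = IPD_pre, TH_pre = TH_pre,
            TH_opt = TH_opt, delta_a = delta_a, delta_p = delta_p,
            h_a = h_a, h_p = h_p, l_a = l_a, l_p = l_p, B = B,
            material = material)
  validate_measurements(m)
  structure(m, class = "valve_measurements")
}

# Bounds used both by the constructor and by the config-file reader; wide
# enough for any plausible adult anatomy, tight enough to catch unit slips.
.meas_bounds <- list(
  MAD_pre = c(10, 80), IPD_pre = c(5, 100), TH_pre = c(1, 40),
  TH_opt = c(0.5, 30), delta_a = c(0, 90), delta_p = c(0, 90),
  h_a = c(5, 100), h_p = c(5, 100), l_a = c(5, 40), l_p = c(5, 40),
  B = c(1, 1e5))

validate_measurements <- function(m) {
  for (key in names(.meas_bounds)) {
    v <- m[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("measurement '%s' must be a single finite number", key),
           call. = FALSE)
    b <- .meas_bounds[[key]]
    if (v <= b[1] || v >= b[2])
      stop(sprintf(
        "measurement '%s' = %g outside plausibility bounds (%g, %g)%s",
        key, v, b[1], b[2],
        if (key %in% c("delta_a", "delta_p")) " degrees" else " mm-based"),
        call. = FALSE)
  }
  if (m$TH_opt >= m$TH_pre)
    stop("TH_opt must be smaller than TH_pre", call. = FALSE)
  if (!inherits(m$material, "chorda_material"))
    stop("material must be a chorda_material object", call. = FALSE)
  invisible(m)
}

#' @export
print.valve_measurements <- function(x, ...) {
  cat("Valve measurements (mm, deg):\n")
  cat(sprintf("  MAD_pre %.1f  IPD_pre %.1f  TH_pre %.1f  TH_opt %.1f\n",
              x$MAD_pre, x$IPD_pre, x$TH_pre, x$TH_opt))
  cat(sprintf("  delta %.1f/%.1f  h %.1f/%.1f  l %.1f/%.1f  B %.0f\n",
              x$delta_a, x$delta_p, x$h_a, x$h_p, x$l_a, x$l_p, x$B))
  cat(sprintf("  chorda: c1 %.1f  c2 %.4f  A_ref %.3f\n",
              x$material$c1, x$material$c2, x$material$A_ref))
  invisible(x)
}

#' Anterior papillary-muscle position from tip, chorda angle and height
#'
#' The anterior chorda leaves the leaflet tip along `(-sin(alpha),
#' cos(alpha))`, so a positive chorda angle offsets the papillary head
#' outboard (away from the valve midline):
#' `m_a = (x_l - (h_a - y_l) tan(alpha), h_a)`.
#'
#' @param tip Anterior tip position `c(x, y)` in the global frame, mm.
#' @param alpha Chorda inclination, rad.
#' @param h Annulus-to-papillary-head height, mm.
#' @return PM position `c(x, y)` in mm.
#' @export
pm_position_anterior <- function(tip, alpha, h) {
  if (h <= tip[2])
    stop("papillary head above the leaflet tip (h <= y_l): invalid geometry",
         call. = FALSE)
  c(tip[1] - (h - tip[2]) * tan(alpha), h)
}

#' Posterior papillary-muscle position (mirrored)
#'
#' The posterior leaflet is solved in its own local frame and mirrored about
#' the vertical through its hinge: with local tip abscissa `x_l`, the global
#' tip sits at `MAD - x_l` and the posterior chorda direction is
#' `(sin(alpha), cos(alpha))`, so
#' `m_p = (MAD - x_l + (h_p - y_l) tan(alpha), h_p)`.
#'
#' @param tip Posterior tip position in the local (mirrored) frame, mm.
#' @param alpha Chorda inclination, rad.
#' @param h Annulus-to-papillary-head height, mm.
#' @param MAD Abscissa of the posterior annular hinge, mm.
#' @return PM position `c(x, y)` in the global frame, mm.
#' @export
pm_position_posterior <- function(tip, alpha, h, MAD) {
  if (h <= tip[2])
    stop("papillary head above the leaflet tip (h <= y_l): invalid geometry",
         call. = FALSE)
  c(MAD - tip[1] + (h - tip[2]) * tan(alpha), h)
}

#' Interpapillary distance
#' @param m_a,m_p Papillary head positions, `c(x, y)` in mm.
#' @return Euclidean distance in mm.
#' @export
interpapillary_distance <- function(m_a, m_p) {
  sqrt(sum((m_a - m_p)^2))
}

#' Assemble a two-leaflet valve configuration
#'
#' Builds the full planar system for given leaflet end-slopes and chorda
#' angles: solves both elasticas, places tips in the global frame (anterior
#' hinge at `(shift_a, 0)`, posterior hinge at `(MAD_pre - r, 0)`), and
#' locates the papillary heads either from the congruency geometry
#' ([pm_position_anterior()] / [pm_position_posterior()]) or at caller-given
#' positions.
#'
#' @param theta_a,theta_p Leaflet end-slopes, rad.
#' @param alpha_a,alpha_p Chorda inclinations, rad.
#' @param meas A [valve_measurements()] object.
#' @param shift_a Anterior annular root shift toward the midline, mm.
#' @param r Posterior annular restriction, mm.
#' @param m_a,m_p Optional papillary positions (global frame); when `NULL`
#'   they are derived from the tips, the chorda angles and the heights.
#' @return An object of class `valve_configuration`.
#' @export
build_configuration <- function(theta_a, theta_p, alpha_a, alpha_p, meas,
                                shift_a = 0, r = 0, m_a = NULL, m_p = NULL) {
  stopifnot(inherits(meas, "valve_measurements"))
  el_a <- solve_elastica(theta_a, alpha_a, meas$l_a, meas$B)
  el_p <- solve_elastica(theta_p, alpha_p, meas$l_p, meas$B)
  a_a <- c(shift_a, 0)
  a_p <- c(meas$MAD_pre - r, 0)
  b_a <- a_a + el_a$tip
  b_p_local <- el_p$tip
  b_p <- c(a_p[1] - b_p_local[["x"]], b_p_local[["y"]])
  if (is.null(m_a)) m_a <- pm_position_anterior(b_a, alpha_a, meas$h_a)
  if (is.null(m_p))
    m_p <- pm_position_posterior(b_p_local, alpha_p, meas$h_p, a_p[1])
  structure(list(
    measurements = meas,
    a_a = a_a, a_p = a_p, shift_a = shift_a, r = r,
    b_a = unname(b_a), b_p = unname(b_p), b_p_local = unname(b_p_local),
    m_a = unname(m_a), m_p = unname(m_p),
    theta_a = theta_a, theta_p = theta_p,
    alpha_a = alpha_a, alpha_p = alpha_p,
    elastica_a = el_a, elastica_p = el_p,
    d = interpapillary_distance(m_a, m_p)
  ), class = "valve_configuration")
}

#' Chorda congruency residuals
#'
#' The chorda must leave each tip toward its papillary head along the
#' direction implied by the load inclination used in the elastica solution:
#' `pi/2 + alpha_a = arg(m_a - b_a)` and `pi/2 - alpha_p = arg(m_p - b_p)`,
#' with `arg` the counterclockwise angle from the global `+x` axis.
#'
#' @param config A [build_configuration()] result.
#' @return Named residual vector (radians), zero at a compatible state.
#' @export
chorda_congruency_residual <- function(config) {
  stopifnot(inherits(config, "valve_configuration"))
  va <- config$m_a - config$b_a
  vp <- config$m_p - config$b_p
  c(anterior = (pi / 2 + config$alpha_a) - atan2(va[2], va[1]),
    posterior = (pi / 2 - config$alpha_p) - atan2(vp[2], vp[1]))
}

#' Node equilibrium residuals at the two leaflet tips
#'
#' At each free edge the chordal Cauchy stress must balance the leaflet end
#' load: `sigma_i - lambda_i P_i / A_ref`, with `lambda_i = |b_i - m_i| /
#' L_c_i`.  Slack chordae (`lambda < 1`) carry zero stress.
#'
#' @param config A [build_configuration()] result.
#' @param P_a,P_p Leaflet end loads, mN.
#' @param L_c_a,L_c_p Reference chorda lengths, mm.
#' @param material A [chorda_material()].
#' @return Named residual vector in mN/mm^2.
#' @export
node_equilibrium_residual <- function(config, P_a, P_p, L_c_a, L_c_p,
                                      material = chorda_material()) {
  stopifnot(inherits(config, "valve_configuration"))
  res_one <- function(b, m, P, L_c) {
    st <- chorda_state(L_c, sqrt(sum((b - m)^2)), material)
    st$sigma - st$lam * P / material$A_ref
  }
  c(anterior = res_one(config$b_a, config$m_a, P_a, L_c_a),
    posterior = res_one(config$b_p, config$m_p, P_p, L_c_p))
}

#' @export
print.valve_configuration <- function(x, ...) {
  cat("Valve configuration\n")
  cat(sprintf("  hinges: a_a = (%.2f, 0), a_p = (%.2f, 0)\n",
              x$a_a[1], x$a_p[1]))
  cat(sprintf("  tips:   b_a = (%.2f, %.2f), b_p = (%.2f, %.2f)\n",
              x$b_a[1], x$b_a[2], x$b_p[1], x$b_p[2]))
  cat(sprintf("  PMs:    m_a = (%.2f, %.2f), m_p = (%.2f, %.2f), d = %.2f\n",
              x$m_a[1], x$m_a[2], x$m_p[1], x$m_p[2], x$d))
  cat(sprintf("  angles: theta %.1f/%.1f deg, alpha %.1f/%.1f deg\n",
              x$theta_a * 180 / pi, x$theta_p * 180 / pi,
              x$alpha_a * 180 / pi, x$alpha_p * 180 / pi))
  invisible(x)
}
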