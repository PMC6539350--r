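# Independent numerical oracles used across the suite.

# Incomplete elliptic integrals by adaptive quadrature (independent of the
# Carlson-form implementation in the package).
quad_F <- function(phi, k)
  integrate(function(t) 1 / sqrt(1 - (k * sin(t))^2), 0, phi,
            rel.tol = 1e-12)$value
quad_E <- function(phi, k)
  integrate(function(t) sqrt(1 - (k * sin(t))^2), 0, phi,
            rel.tol = 1e-12)$value

# Two-point elastica integration: the equilibrium field B theta'' =
# -P cos(theta - alpha) with theta(0) = 0 and the analytic root curvature as
# initial slope, integrated as an IVP with deSolve.  Returns positions and
# tangent angle at the requested abscissae (dimensionless lengths).
ode_elastica <- function(theta_l, alpha, s_out) {
  core <- mvelastica:::c_elastica_core(theta_l, alpha)
  stopifnot(core[["ok"]] == 1)
  om <- core[["omega"]]
  th0p <- 2 * core[["k"]] * om * cos(core[["phi_alpha"]])
  rhs <- function(t, y, p)
    list(c(cos(y[3]), sin(y[3]), y[4], -om^2 * cos(y[3] - alpha)))
  out <- deSolve::ode(c(x = 0, y = 0, th = 0, thp = th0p),
                      unique(c(0, s_out)), rhs, NULL,
                      rtol = 1e-11, atol = 1e-12)
  out[match(s_out, out[, "time"]), c("x", "y", "th", "thp"), drop = FALSE]
}

# Bisection solve of the chordal equilibrium, independent of uniroot.
bisect_stretch <- function(P, mat, lo = 1, hi = 3, iters = 200) {
  f <- function(lam)
    mat$c1 * (exp(mat$c2 * (lam^2 - 1) / 2) - 1) - lam * P / mat$A_ref
  while (f(hi) < 0) hi <- hi * 1.5
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Table-style case measurements shared by several tests.
case_meas <- function() case_study_measurements()

# A synthetic patient with mild tethering for which the complete
# approximation to a 10 mm interpapillary distance is attainable.
mild_tethering_measurements <- function()
  valve_measurements(MAD_pre = 40, IPD_pre = 35, TH_pre = 9.7, TH_opt = 5,
                     h_a = 34, h_p = 30)
mild_tethering_windows <- function() compatibility_windows(dTH = 0.5, dIPD = 1)
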