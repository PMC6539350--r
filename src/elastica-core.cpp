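// Numerical core: Carlson symmetric elliptic integrals, the incomplete
// Legendre integrals F and E built on them, the Jacobi amplitude, and the
// closed-form elastica kinematics with the two scalar root solves that the
// higher-level R code calls inside sampling loops.
//
// Conventions (shared with the R layer):
//   * lengths are scaled by the leaflet length l, so the tip is shape(1);
//   * theta_l is the free-edge tangent angle w.r.t. the annular (x) axis;
//   * alpha is the end-load inclination w.r.t. the apical (y) axis, with
//     the load direction (-sin(alpha), +cos(alpha)) in the leaflet frame;
//   * eccentricity 2 k^2 = 1 + sin(theta_l - alpha),
//     amplitude 2 k^2 sin^2(phi_alpha) = 1 - sin(alpha),
//     load frequency omega = K[k] - F[phi_alpha, k] (so P = B omega^2 / l^2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------- Carlson RF
// Duplication algorithm; relative accuracy ~1e-13 on the domain used here.
static double carlson_rf(double x, double y, double z) {
  double mu, X, Y, Z;
  for (int it = 0; it < 200; ++it) {
    double sx = std::sqrt(x), sy = std::sqrt(y), sz = std::sqrt(z);
    double lam = sx * sy + sy * sz + sz * sx;
    x = 0.25 * (x + lam);
    y = 0.25 * (y + lam);
    z = 0.25 * (z + lam);
    mu = (x + y + z) / 3.0;
    X = 1.0 - x / mu;
    Y = 1.0 - y / mu;
    Z = 1.0 - z / mu;
    double err = std::max(std::fabs(X), std::max(std::fabs(Y), std::fabs(Z)));
    if (err < 0.0015) break;
  }
  double e2 = X * Y - Z * Z;
  double e3 = X * Y * Z;
  return (1.0 - e2 / 10.0 + e3 / 14.0 + e2 * e2 / 24.0 -
          3.0 * e2 * e3 / 44.0) / std::sqrt(mu);
}

// ---------------------------------------------------------------- Carlson RD
static double carlson_rd(double x, double y, double z) {
  double sum = 0.0, fac = 1.0, mu, X, Y, Z;
  for (int it = 0; it < 200; ++it) {
    double sx = std::sqrt(x), sy = std::sqrt(y), sz = std::sqrt(z);
    double lam = sx * sy + sy * sz + sz * sx;
    sum += fac / (sz * (z + lam));
    fac *= 0.25;
    x = 0.25 * (x + lam);
    y = 0.25 * (y + lam);
    z = 0.25 * (z + lam);
    mu = (x + y + 3.0 * z) / 5.0;
    X = (mu - x) / mu;
    Y = (mu - y) / mu;
    Z = (mu - z) / mu;
    double err = std::max(std::fabs(X), std::max(std::fabs(Y), std::fabs(Z)));
    if (err < 0.0015) break;
  }
  double ea = X * Y - 6.0 * Z * Z;
  double eb = (3.0 * X * Y - 8.0 * Z * Z) * Z;
  double ec = 3.0 * (X * Y - Z * Z) * Z * Z;
  double ed = X * Y * Z * Z * Z;
  return 3.0 * sum +
         fac * (1.0 - 3.0 * ea / 14.0 + eb / 6.0 + 9.0 * ea * ea / 88.0 -
                3.0 * ec / 22.0 - 9.0 * eb * Z / 52.0 + 3.0 * ed / 26.0) /
             (mu * std::sqrt(mu));
}

// Legendre forms, modulus k (not the parameter m = k^2), phi in [0, pi/2].
static double ell_F(double phi, double k) {
  double sp = std::sin(phi), cp = std::cos(phi);
  double q = 1.0 - k * k * sp * sp;
  return sp * carlson_rf(cp * cp, q, 1.0);
}

static double ell_E(double phi, double k) {
  double sp = std::sin(phi), cp = std::cos(phi);
  double q = 1.0 - k * k * sp * sp;
  return sp * carlson_rf(cp * cp, q, 1.0) -
         (k * k * sp * sp * sp / 3.0) * carlson_rd(cp * cp, q, 1.0);
}

static double ell_K(double k) { return carlson_rf(0.0, 1.0 - k * k, 1.0); }

static double ell_Ecomp(double k) {
  return carlson_rf(0.0, 1.0 - k * k, 1.0) -
         (k * k / 3.0) * carlson_rd(0.0, 1.0 - k * k, 1.0);
}

// Jacobi amplitude on u in [0, K(k)]: monotone inverse of F(., k), solved by
// a Newton iteration with bisection safeguard (F' = 1/sqrt(1 - k^2 sin^2)).
static double jacobi_am_principal(double u, double k) {
  if (u <= 0.0) return 0.0;
  double K = ell_K(k);
  if (u >= K) return PI_ / 2.0;
  double lo = 0.0, hi = PI_ / 2.0;
  double phi = (u / K) * PI_ / 2.0;
  for (int it = 0; it < 100; ++it) {
    double f = ell_F(phi, k) - u;
    if (f > 0.0) hi = phi; else lo = phi;
    double sp = std::sin(phi);
    double dphi = f * std::sqrt(1.0 - k * k * sp * sp);
    double next = phi - dphi;
    if (next <= lo || next >= hi) next = 0.5 * (lo + hi);
    if (std::fabs(next - phi) < 1e-15) { phi = next; break; }
    phi = next;
  }
  return phi;
}

// ------------------------------------------------------------ R-facing math
// [[Rcpp::export]]
NumericVector c_ellF(NumericVector phi, NumericVector k) {
  int n = std::max(phi.size(), k.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ell_F(phi[i % phi.size()], k[i % k.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector c_ellE(NumericVector phi, NumericVector k) {
  int n = std::max(phi.size(), k.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = ell_E(phi[i % phi.size()], k[i % k.size()]);
  return out;
}

// [[Rcpp::export]]
NumericVector c_ellK(NumericVector k) {
  NumericVector out(k.size());
  for (int i = 0; i < k.size(); ++i) out[i] = ell_K(k[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector c_ellEcomp(NumericVector k) {
  NumericVector out(k.size());
  for (int i = 0; i < k.size(); ++i) out[i] = ell_Ecomp(k[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector c_am(NumericVector u, NumericVector k) {
  int n = std::max(u.size(), k.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = jacobi_am_principal(u[i % u.size()], k[i % k.size()]);
  return out;
}

// -------------------------------------------------------------- elastica
// Validity of the (theta_l, alpha) pair for a tensile end load.
// Returns k in (0, 1) and phi_alpha in [0, pi/2], or NaN flags.
struct ElCore {
  double k, phia, om, xt, yt, kap0;
  bool ok;
};

static ElCore elastica_core(double theta_l, double alpha) {
  ElCore c;
  c.ok = false;
  c.k = c.phia = c.om = c.xt = c.yt = c.kap0 = NA_REAL;
  double k2 = 0.5 * (1.0 + std::sin(theta_l - alpha));
  if (k2 <= 1e-14 || k2 >= 1.0 - 1e-12) return c;
  double k = std::sqrt(k2);
  double arg = (1.0 - std::sin(alpha)) / (2.0 * k2);
  if (arg < 0.0 || arg > 1.0) return c;
  double phia = std::asin(std::sqrt(arg));
  double Fa = ell_F(phia, k);
  double om = ell_K(k) - Fa;
  c.k = k; c.phia = phia; c.om = om;
  if (om < 1e-10) {           // unloaded straight limit (theta_l == alpha)
    c.xt = 1.0; c.yt = 0.0; c.kap0 = 0.0; c.ok = true;
    return c;
  }
  double Ea = ell_E(phia, k);
  double G = ell_K(k) - 2.0 * ell_Ecomp(k) + 2.0 * Ea - Fa;
  double ca = std::cos(alpha), sa = std::sin(alpha), cpa = std::cos(phia);
  c.xt = (2.0 * k * ca * cpa - sa * G) / om;
  c.yt = (ca * G + 2.0 * k * sa * cpa) / om;
  c.kap0 = 2.0 * k * om * cpa;   // dimensionless root curvature l * kappa(0)
  c.ok = true;
  return c;
}

// [[Rcpp::export]]
NumericVector c_elastica_core(double theta_l, double alpha) {
  ElCore c = elastica_core(theta_l, alpha);
  NumericVector out = NumericVector::create(
      _["k"] = c.k, _["phi_alpha"] = c.phia, _["omega"] = c.om,
      _["x_tip"] = c.xt, _["y_tip"] = c.yt, _["kappa0"] = c.kap0,
      _["ok"] = c.ok ? 1.0 : 0.0);
  return out;
}

// Deformed shape (and tangent angle) at curvilinear abscissae s in [0, 1],
// lengths scaled by l.
// [[Rcpp::export]]
NumericMatrix c_elastica_shape(NumericVector s, double theta_l, double alpha) {
  ElCore c = elastica_core(theta_l, alpha);
  if (!c.ok) stop("invalid (theta_l, alpha) pair for a tensile elastica");
  int n = s.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("x", "y", "theta");
  if (c.om < 1e-10) {
    for (int i = 0; i < n; ++i) { out(i, 0) = s[i]; out(i, 1) = 0.0; out(i, 2) = 0.0; }
    return out;
  }
  double Fa = ell_F(c.phia, c.k), Ea = ell_E(c.phia, c.k);
  double ca = std::cos(alpha), sa = std::sin(alpha), cpa = std::cos(c.phia);
  for (int i = 0; i < n; ++i) {
    double phis = jacobi_am_principal(c.om * s[i] + Fa, c.k);
    double Fs = ell_F(phis, c.k), Es = ell_E(phis, c.k);
    double G = Fs - 2.0 * Es + 2.0 * Ea - Fa;
    double dc = cpa - std::cos(phis);
    out(i, 0) = (2.0 * c.k * ca * dc - sa * G) / c.om;
    out(i, 1) = (ca * G + 2.0 * c.k * sa * dc) / c.om;
    double sarg = 2.0 * c.k * c.k * std::sin(phis) * std::sin(phis) - 1.0;
    sarg = std::max(-1.0, std::min(1.0, sarg));
    out(i, 2) = alpha + std::asin(sarg);
  }
  return out;
}

// First sign change of f over a scan grid, refined by bisection.
template <typename F>
static double first_root(F f, double lo, double hi, int n_scan) {
  double prev_t = NA_REAL, prev_v = NA_REAL;
  double root = NA_REAL;
  for (int i = 0; i <= n_scan; ++i) {
    double t = lo + (hi - lo) * i / n_scan;
    double v = f(t);
    if (std::isnan(v)) { prev_t = NA_REAL; continue; }
    if (!std::isnan(prev_v)) {
      if (v == 0.0) return t;
      if (prev_v * v < 0.0) {
        double a = prev_t, b = t, fa = prev_v;
        for (int it = 0; it < 90; ++it) {
          double m = 0.5 * (a + b), fm = f(m);
          if (std::isnan(fm)) break;
          if (fa * fm <= 0.0) b = m; else { a = m; fa = fm; }
        }
        root = 0.5 * (a + b);
        return root;
      }
    }
    prev_t = t; prev_v = v;
  }
  return root;
}

// Solve theta_l so that the tip satisfies y = x tan(delta) (leaflet-angle
// congruence). Returns NA when no root exists in (0, pi/2).
// [[Rcpp::export]]
double c_theta_from_delta(double delta, double alpha) {
  double td = std::tan(delta);
  auto f = [&](double th) -> double {
    ElCore c = elastica_core(th, alpha);
    if (!c.ok) return NA_REAL;
    return c.yt - c.xt * td;
  };
  return first_root(f, 1e-6, PI_ / 2.0 - 1e-6, 140);
}

// Solve theta_l so that the dimensionless tip height equals y_over_l.
// [[Rcpp::export]]
double c_theta_from_y(double y_over_l, double alpha) {
  auto f = [&](double th) -> double {
    ElCore c = elastica_core(th, alpha);
    if (!c.ok) return NA_REAL;
    return c.yt - y_over_l;
  };
  return first_root(f, 1e-6, PI_ / 2.0 - 1e-6, 140);
}
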