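#' Fung-type chordal material
#'
#' One-dimensional incompressible Fung model of a chorda tendinea with
#' strain-energy density `psi(eps) = (c1/c2) (exp(c2 eps) - 1) - c1 eps`
#' in terms of the Green strain `eps = (lambda^2 - 1)/2`.  Defaults are the
#' literature constants used throughout the case study.
#'
#' @param c1 Stress-like constant, mN/mm^2.
#' @param c2 Dimensionless exponent.
#' @param A_ref Reference cross-sectional area, mm^2.
#' @return An object of class `chorda_material`.
#' @export
chorda_material <- function(c1 = 352.4, c2 = 0.1907, A_ref = 0.197) {
  stopifnot(is.numeric(c1), c1 > 0, is.numeric(c2), c2 > 0,
            is.numeric(A_ref), A_ref > 0)
  structure(list(c1 = c1, c2 = c2, A_ref = A_ref), class = "chorda_material")
}

#' Green strain from stretch
#' @param lam Stretch `lambda = l_c / L_c`, positive.
#' @return `eps = (lambda^2 - 1)/2`.
#' @export
green_strain <- function(lam) {
  stopifnot(all(lam > 0))
  (lam^2 - 1) / 2
}

#' Chordal Cauchy stress
#'
#' `sigma = d psi / d eps = c1 (exp(c2 eps) - 1)`; related to the nominal
#' stress by `sigma = T lambda`.
#'
#' @param eps Green strain, greater than -1/2.
#' @param material A [chorda_material()].
#' @return Cauchy stress in mN/mm^2.
#' @export
cauchy_stress <- function(eps, material = chorda_material()) {
  stopifnot(inherits(material, "chorda_material"), all(eps > -0.5))
  material$c1 * (exp(material$c2 * eps) - 1)
}

#' Chordal strain-energy density
#' @inheritParams cauchy_stress
#' @return `psi(eps) >= 0`.
#' @export
strain_energy <- function(eps, material = chorda_material()) {
  stopifnot(inherits(material, "chorda_material"), all(eps > -0.5))
  with(material, (c1 / c2) * (exp(c2 * eps) - 1) - c1 * eps)
}

#' Equilibrium stretch of a chorda under a given end load
#'
#' Solves `c1 (exp(c2 (lambda^2 - 1)/2) - 1) = lambda P / A_ref` for the
#' unique tensile stretch `lambda >= 1`.  The left side is strictly convex
#' and increasing in `lambda`, so the root is unique; the bracket grows
#' automatically from `[1, 3]` if needed.
#'
#' @param P Tensile end load in mN (non-negative).
#' @param material A [chorda_material()].
#' @return Equilibrium stretch `lambda >= 1`.
#' @export
equilibrium_stretch <- function(P, material = chorda_material()) {
  stopifnot(inherits(material, "chorda_material"), is.numeric(P),
            length(P) == 1L, P >= 0)
  if (P == 0) return(1)
  f <- function(lam)
    cauchy_stress(green_strain(lam), material) - lam * P / material$A_ref
  hi <- 3
  while (f(hi) < 0) {
    hi <- hi * 1.5
    if (hi > 1e4)
      stop("no equilibrium stretch below lambda = 1e4 (non-physical load)",
           call. = FALSE)
  }
  uniroot(f, c(1, hi), tol = 1e-13)$root
}

#' Reference chorda length by pull-back
#'
#' `L_c = l_c_pre / lambda_pre`: the unloaded length recovered from the
#' observed (loaded) preoperative length and the identified preoperative
#' stretch.
#'
#' @param l_c_pre Observed current length, mm.
#' @param lam_pre Preoperative stretch (>= 1).
#' @return Reference length `L_c` in mm.
#' @export
reference_length <- function(l_c_pre, lam_pre) {
  stopifnot(all(l_c_pre > 0), all(lam_pre >= 1))
  l_c_pre / lam_pre
}

#' State of one chorda at a given current length
#'
#' Computes stretch, Green strain, Cauchy and nominal stress.  Chordae are
#' tension-only: a current length below the reference length marks the
#' chorda as slack and carries zero stress.
#'
#' @param L_c Reference length, mm.
#' @param l_c Current length, mm.
#' @param material A [chorda_material()].
#' @return An object of class `chorda_state` with fields `L_c`, `l_c`,
#'   `lam`, `eps`, `sigma`, `T` and `slack`.
#' @export
chorda_state <- function(L_c, l_c, material = chorda_material()) {
  stopifnot(L_c > 0, l_c > 0)
  lam <- l_c / L_c
  slack <- lam < 1
  eps <- green_strain(lam)
  sigma <- if (slack) 0 else cauchy_stress(eps, material)
  structure(list(L_c = L_c, l_c = l_c, lam = lam, eps = eps,
                 sigma = sigma, T = if (slack) 0 else sigma / lam,
                 slack = slack, material = material),
            class = "chorda_state")
}

#' @export
print.chorda_state <- function(x, ...) {
  cat(sprintf(
    "Chorda state: L_c = %.3f mm, l_c = %.3f mm, lambda = %.4f%s\n",
    x$L_c, x$l_c, x$lam, if (x$slack) " (slack)" else ""))
  cat(sprintf("  eps = %.4f, sigma = %.3f mN/mm^2, T = %.3f mN/mm^2\n",
              x$eps, x$sigma, x$T))
  invisible(x)
}
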