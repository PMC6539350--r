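---
title: "A planar elastica model of mitral valve repair: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A planar elastica model of mitral valve repair: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvelastica)
```

## The problem

Ischemic mitral regurgitation (IMR) follows post-infarction remodelling of
the left ventricle: the papillary muscles (PMs) are displaced apically and
laterally, the chordae tendineae tether the leaflets, and the valve no
longer coapts.  Surgical correction combines a restrictive annuloplasty
(RA), which shortens the antero-posterior annular diameter by `r`
millimetres, with a papillary muscle approximation (PMA), which relocates
the PM heads.  The planning question this package addresses is quantitative:
given a patient's echocardiographic measurements, how much restriction is
needed to restore coaptation, where should the PMs be placed to minimize
chordal loading, and how do the leaflet root moments and chordal stresses
change?

`mvelastica` implements a two-dimensional analytical model of this system
and its two solution procedures: *identification* of the preoperative
configuration from clinical measurements, and *prediction* of the
postoperative configuration under three repair scenarios.

## The mechanical model

### Leaflets: inextensible elastica

Each leaflet is a planar inextensible cantilever of length $l$ and bending
stiffness $B$, clamped horizontally at its annular hinge and loaded at the
free edge by the tension of one chorda.  The load has magnitude $P$ and is
inclined by $\alpha$ from the apical ($y$) axis, acting along
$(-\sin\alpha, \cos\alpha)$ in the leaflet frame (for $\alpha > 0$ the pull
has a component back toward the hinge).  With the free-edge tangent angle
$\theta_l$, the exact large-deflection solution is elliptic-integral
closed form.  Writing $F$, $E$ for the incomplete Legendre integrals and
$\mathrm{am}$ for the Jacobi amplitude,

$$2k^2 = 1 + \sin(\theta_l - \alpha), \qquad
  2k^2\sin^2\varphi_\alpha = 1 - \sin\alpha, \qquad
  \omega = K[k] - F[\varphi_\alpha, k],$$

and $P = B\,\omega^2/l^2$.  The amplitude along the arclength $s \in [0,1]$
is $\varphi(s) = \mathrm{am}[\omega s + F[\varphi_\alpha,k],\,k]$, from
which the parametric shape $(x(s), y(s))$ follows.  Useful identities that
the implementation exploits and the tests verify:

* the tangent angle satisfies $2k^2\sin^2\varphi(s) = 1 + \sin(\theta(s) -
  \alpha)$, so $\theta(0) = 0$ (clamped) and $\theta(1) = \theta_l$;
* the dimensionless curvature is $l\,\kappa(s) = 2k\omega\cos\varphi(s)$,
  giving the root bending moment $M = 2k\omega B\cos\varphi_\alpha / l$ and
  an identically zero free-edge curvature (end-point load);
* $\omega \to 0$ iff $\theta_l \to 0$: the unloaded leaflet is the straight
  horizontal beam, returned analytically (the $0/0$ form of the shape
  formulas is never evaluated below $\omega < 10^{-10}$).

The closed form is checked against an independent integration of the
equilibrium field $B\,\theta'' = -P\cos(\theta - \alpha)$ (`deSolve`) to
$10^{-5}\,l$ in the sup-norm over 200 random angle pairs, and against the
linear Euler–Bernoulli deflection $P l^3 / 3B$ for shallow angles.

### Chordae: Fung-type tension-only elements

A chorda with reference length $L_c$ and current length $l_c$ has stretch
$\lambda = l_c / L_c$, Green strain $\varepsilon = (\lambda^2 - 1)/2$, and
Cauchy stress

$$\sigma = c_1\left(e^{c_2\varepsilon} - 1\right) = T\lambda,$$

with $T = P/A_{\mathrm{ref}}$ the nominal stress.  Defaults
($c_1 = 352.4$ mN/mm², $c_2 = 0.1907$, $A_{\mathrm{ref}} = 0.197$ mm²) are
the literature constants used in the case study; all three are configurable
per patient.  Chordae are tension-only: a current length below $L_c$ marks
the element slack with zero stress.  The node equilibrium at each leaflet
tip, $\sigma = \lambda P / A_{\mathrm{ref}}$, has a unique tensile root
because $\sigma(\lambda)$ is strictly convex increasing; it is solved by
safeguarded bracketing to $10^{-13}$.

Note that with $c_2 \approx 0.19$ this material is very compliant: at the
case-study loads the equilibrium stretches reach $\lambda \approx 2$–$2.7$
on the posterior chorda.  Chordal stress–strain exponents reported
elsewhere in the literature are two orders of magnitude stiffer; the
compliance of this parameterization propagates into the predicted
postoperative PM positions (see *Known limitations*).

### Assembly

The global frame puts the anterior hinge at the origin, the posterior hinge
at $(\mathrm{MAD}, 0)$, and $y$ toward the apex.  The posterior leaflet is
solved in its own mirrored frame.  Each chorda connects a leaflet tip
$b_i$ to its PM head $m_i$; congruency requires the chordal direction to
match the load inclination used in the elastica solution,

$$\tfrac{\pi}{2} + \alpha^a = \arg(m^a - b^a), \qquad
  \tfrac{\pi}{2} - \alpha^p = \arg(m^p - b^p),$$

with $\arg$ the counterclockwise angle from $+x$.  Positive $\alpha$ places
a PM *outboard* of its tip.  (The alternative sign convention, PMs inboard,
caps the attainable interpapillary distance at roughly half the measured
values and is therefore rejected; this choice makes the congruency and the
PM-position formulas mutually consistent.)  PM heights $h$ are measured
from the annular plane, so a PM sits at $y = h$.

## Preoperative identification

Inputs are the clinical measurements (`valve_measurements()`): annular
diameter MAD, end-diastolic interpapillary distance IPD, tenting height TH,
leaflet angles $\delta^a, \delta^p$, PM heights $h^a, h^p$, leaflet lengths
and stiffness, chordal constants.  The identification draws chorda angles
$\alpha^a, \alpha^p$ uniformly on $(1^\circ, 60^\circ)$, solves each
leaflet's end-slope from the leaflet-angle congruence $y_l = x_l\tan\delta$
(bracketed scalar root), and accepts the first draw whose tip heights fall
within $\mathrm{TH} \pm \Delta_{TH}$ and whose interpapillary distance
(from the PM positions implied by the chordal rays) falls within
$\mathrm{IPD} \pm \Delta_{IPD}$.  Window half-widths default to the cohort
standard deviations of the reference dataset (0.13 mm and 0.39 mm) and are
configurable.  Acceptance draws are reproducible given the seed, which is
recorded with the iteration count in the result.

Two structural properties of this inverse problem deserve emphasis,
because they shape everything downstream:

1. **Tip heights are bounded by the leaflet geometry.**  Under the
   congruence the tip lies on the ray at angle $\delta$, so its height is
   strictly below $l\sin\delta$ — about 9.4 mm (anterior) and 10.1 mm
   (posterior) for the reference measurements, whereas the measured tenting
   height is 12.4 mm.  The reference measurement set is therefore mutually
   incompatible (it also violates the tenting-triangle identity
   $\mathrm{TH} = \mathrm{MAD}/(\cot\delta^a + \cot\delta^p)$).  Rather
   than looping forever, `identify_preop()` scans the attainable range of
   each windowed quantity first; windows no draw can satisfy are reported,
   flagged in the returned object, and excluded from the acceptance test.
   For the reference case the procedure then effectively accepts on the
   IPD window, which *is* attainable.
2. **The chorda angles are only partially identified.**  The tip positions
   depend on $\delta$ but barely on $\alpha$ (variation below 0.25 mm over
   the whole sampling range), so the tenting-height condition carries no
   information about $\alpha$, and one IPD equation constrains two angles:
   the accepted draws populate a one-parameter ridge.  Chordal loads vary
   by tens of percent along it.  This under-determination is intrinsic to
   the measurement set, not to the search; it is why repeated
   identifications scatter, why the package reports medians over
   identification repetitions for headline numbers, and why a
   forward-generated "truth" configuration is recovered only up to the
   ridge (its windows are recovered; its chordal stresses are not, in
   general).

`finalize_preop()` completes an accepted geometry: leaflet loads
$P = B\omega^2/l^2$, equilibrium stretches, reference chorda lengths by
pull-back $L_c = |b - m|/\lambda$, root moments, and nominal stresses.

## Postoperative prediction

The postoperative state must satisfy, per leaflet, (i) *coaptation*
$y_l = \mathrm{TH}^{opt}$, (ii) *congruency* of the chordal direction, and
(iii) *node equilibrium*; plus the annular constraint
$x_l^a + x_l^p = \mathrm{MAD} - r$ — seven equations.  The restriction
vector $\{r, 0\}$ is applied to the posterior hinge; PM displacements are
parameterized as $u^a = (u_x^a, \zeta^a u_x^a)$ and
$u^p = (-u_x^p, \zeta^p u_x^p)$, so each orientation coefficient $\zeta$
fixes a displacement direction and the magnitude is an unknown.

**Solution strategy.**  Because the two tips coincide at the coaptation
point, the annular equation can be eliminated: the system splits into an
anterior and a posterior block of three equations in three unknowns.
Within a block, the chorda angle $\alpha$ is the outer unknown: the
end-slope follows from the coaptation height (bracketed root), the PM
displacement magnitude from congruency (ray–line intersection, closed
form), and the remaining scalar equilibrium residual is driven to zero by
Brent's method over a bracketing scan of $\alpha \in (-75^\circ,
80^\circ)$.  All equilibria found on the scan are retained; when several
exist the least-stressed one is returned (a documented tie-break —
continuation from the preoperative state was evaluated as an alternative
and reproduces the same branches while folding for some inputs).  Every
reported solution is verified against the fully assembled scaled
seven-component residual vector (`postop_residuals()`), with equilibrium
scaled by $c_1$, lengths by MAD, angles in radians; the acceptance level is
$10^{-8}$ and solutions typically reach $10^{-14}$.

**Scenarios.**

* `optimized_pma`: orientations $(\zeta^a, \zeta^p)$ given; the seven
  unknowns $(\theta^a, \theta^p, \alpha^a, \alpha^p, u_x^a, u_x^p, r)$
  solved as above.  `optimize_pma()` wraps this in a seeded random search
  over orientation pairs, keeping the solution that minimizes the chordal
  nominal stress.  Orientations are sampled uniformly on $[-3, 3]$: the
  sign span matters, because displacements with positive $\zeta$ (apically
  directed) admit no coapted equilibrium for severely tethered inputs,
  while the solutions that do exist — and the reported postoperative
  PM-to-annulus distances, which are *smaller* than the preoperative ones —
  require annulus-ward (negative-$\zeta\,u_x$) motion.  The API default
  objective is the worst of the two chordal stresses; the case-study runner
  minimizes their *sum*, because when one chorda dominates the max
  objective leaves the other PM's position set by search noise rather than
  by optimality — a determinism argument, recorded here as the package's
  design choice.
* `ra_only`: the PMs stay put and the restriction is split per side,
  $r = r_a + r_p$, each side's hinge shift becoming its third unknown
  (the split resolves an otherwise over-determined system; the residual
  tip-abscissa gap between the two independently solved sides is reported
  as a diagnostic).  With the compliant default chordae this scenario's
  equilibria all carry *negative* restriction — annuloplasty alone cannot
  re-establish coaptation without letting the annulus widen — which is the
  model's sharpened version of the clinical observation that isolated RA
  under-treats severe tethering.
* `complete_pma`: the postoperative IPD is prescribed (default 10 mm).
  The extra equation is balanced by solving a *shared* orientation
  coefficient $\zeta^a = \zeta^p = \zeta$ as the eighth unknown (outer
  scalar root in $\zeta$).  Prescriptions outside the attainable range of
  the equilibrium manifold either error with the attainable interval
  (`ipd_mode = "strict"`) or return the nearest attainable configuration,
  flagged (`ipd_mode = "nearest"`, used by `compare_scenarios()`).  For
  the reference case the 10 mm prescription is unattainable (the
  equilibrium PM loci cannot approach closer than ≈14 mm); it is attainable
  for milder tethering, where the solver meets it to $10^{-8}$.

`indicators()` reports the non-dimensional effectiveness ratios — root
moment $M_r$, chordal nominal stress $T_r$, chordal stretch $\lambda_r$,
postoperative over preoperative, per leaflet — and `compare_scenarios()`
tabulates them for the three scenarios from one preoperative state.  In
the reference case the relative ordering
$T_r(\mathrm{RA}) \ge T_r(\mathrm{complete}) \ge T_r(\mathrm{optimized})$
holds per leaflet across seeds; the absolute statement
$T_r(\mathrm{RA}) \ge 1$ holds only on the leaflet whose PM sits far
outboard, because a near-vertical chorda re-balances a coapted leaflet with
little extra stretch.  Which leaflet that is depends on where the
identification lands on the ridge.

## Numerical choices

* Incomplete elliptic integrals use Carlson symmetric forms $R_F$, $R_D$
  (duplication algorithm, relative accuracy ~$10^{-12}$); the Jacobi
  amplitude inverts $F$ by a Newton iteration with bisection safeguard.
  All are implemented in C++ for the inner sampling loops and
  cross-checked against quadrature and `pracma` in the tests.
* The eccentricity is guarded away from $k = 1$ (where $K$ diverges,
  i.e. $\theta_l - \alpha \to \pi/2$); invalid angle pairs inside solver
  loops yield large residuals rather than errors.
* Scalar roots (end-slope from leaflet angle or coaptation height,
  equilibrium over $\alpha$, shared $\zeta$) use scan-and-bisect/Brent
  brackets: 140-point scans for the end-slope, 130 for $\alpha$, 0.1-wide
  steps for $\zeta$; tolerances $10^{-11}$–$10^{-13}$.
* Identification defaults: `max_iter = 10000`, acceptance typically within
  a few hundred draws for the reference case.

## Problem sizes

The shipped defaults are the sizes used throughout the tests and the
reproduction script: 200 orientation draws per postoperative search, five
identification repetitions pooled by the median for headline quantities,
50 forward-generated patients in the recovery study, 200 random angle pairs
in the elastica-versus-ODE comparison, and 1000 random loads in the chordal
equilibrium check.  These choices keep a full reproduction run at about a
minute on one CPU; enlarging them changes fourth decimals, not conclusions.

## What the synthetic cohort does and does not emulate

`generate_cohort()` draws each measurement independently from a truncated
normal with the reference cohort's mean and standard deviation.  It
reproduces marginal variability but not the correlations of real anatomy
(larger ventricles have both wider annuli and deeper PMs), nor measurement
error structure, nor asymmetric-tethering phenotypes.  Tests passing on
synthetic cohorts therefore establish the solvers' contracts — constraint
satisfaction, determinism, orderings — not clinical validity of the model
on any real population.

## Known limitations

* The model is planar and quasi-static, with a single effective chorda per
  leaflet and no systolic pressure load on the leaflets; it represents the
  intraoperative (unloaded) setting.
* The reference measurement set is internally inconsistent (tenting height
  versus leaflet angles and lengths), and the identification is
  under-determined along a chorda-angle ridge; both are handled explicitly
  and reported, but they bound the reproducibility of any quantity that
  depends on the preoperative chordal loads.
* The default chordal constants are very compliant (see above); predicted
  preoperative stretches far exceed physiologic chordal strains, and the
  postoperative PM positions inherit the resulting short reference lengths.
  Stiffer constants can be supplied via the patient configuration.
* The anterior root moment of any coapted postoperative state is nearly
  invariant (~32–34 mN·mm here), so the anterior moment reduction is
  essentially set by the preoperative moment, which the leaflet-angle
  congruence caps at ~50 mN·mm: anterior reductions beyond ~35% are
  unreachable for these measurements.
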