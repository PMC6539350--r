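# Closed-form elastica: eccentricity/amplitude/load algebra, shape against
# an independent ODE integration, linear-beam limit, statics identities.

deg <- pi / 180

test_that("eccentricity and reference amplitude follow the defining algebra", {
  expect_equal(eccentricity_from_angles(0.4, 0.4), sqrt(2) / 2)
  expect_equal(eccentricity_from_angles(pi / 2 - 1e-9, 0), 1, tolerance = 1e-8)
  th <- 32.6 * deg; al <- 10 * deg
  expect_equal(eccentricity_from_angles(th, al),
               sqrt((1 + sin(th - al)) / 2))
  expect_equal(reference_amplitude(sqrt(2) / 2, 0), pi / 2)
  expect_equal(reference_amplitude(0.9, pi / 2), 0)
  k <- eccentricity_from_angles(56.8 * deg, 20 * deg)
  expect_equal(reference_amplitude(k, 20 * deg),
               asin(sqrt((1 - sin(20 * deg)) / (2 * k^2))))
  expect_error(reference_amplitude(0.4, -0.8), "amplitude argument")
})

test_that("load frequency equals the elliptic-integral difference", {
  expect_equal(load_frequency(sqrt(2) / 2, pi / 2), 0, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:10) {
    k <- runif(1, 0.2, 0.95); phia <- runif(1, 0, pi / 2)
    expect_equal(load_frequency(k, phia),
                 quad_F(pi / 2, k) - quad_F(phia, k), tolerance = 1e-9)
  }
})

test_that("tip load is B omega^2 / l^2, linear in B, zero when unloaded", {
  expect_equal(tip_load(elastica_params(18, 500, 0, 0.3)), 0,
               tolerance = 1e-15)
  p1 <- tip_load(elastica_params(18, 500, 0.8, 0.1))
  p2 <- tip_load(elastica_params(18, 1000, 0.8, 0.1))
  expect_equal(p2, 2 * p1)
  sol <- solve_elastica(0.8, 0.1, 18, 500)
  expect_equal(sol$P, 500 * sol$omega^2 / 18^2)
  expect_equal(tip_load(sol$params), sol$P)
})

test_that("amplitude field starts at phi_alpha, ends consistent with omega", {
  sol <- solve_elastica(50 * deg, 15 * deg, 18, 500)
  expect_equal(amplitude_at(0, sol$omega, sol$phi_alpha, sol$k),
               sol$phi_alpha, tolerance = 1e-12)
  phi1 <- amplitude_at(1, sol$omega, sol$phi_alpha, sol$k)
  expect_equal(quad_F(phi1, sol$k),
               sol$omega + quad_F(sol$phi_alpha, sol$k), tolerance = 1e-9)
  # mid-span values invert F
  for (s in c(0.25, 0.5, 0.75)) {
    phis <- amplitude_at(s, sol$omega, sol$phi_alpha, sol$k)
    expect_equal(quad_F(phis, sol$k),
                 sol$omega * s + quad_F(sol$phi_alpha, sol$k),
                 tolerance = 1e-9)
  }
})

test_that("shape matches the ODE oracle pointwise and is inextensible", {
  set.seed(22)
  s <- seq(0, 1, length.out = 41)
  for (i in 1:12) {
    th <- runif(1, 5, 80) * deg
    al <- runif(1, 0, 60) * deg
    sol <- solve_elastica(th, al, 18, 500)
    if (sol$omega < 1e-6) next
    sh <- elastica_shape(sol, s)
    od <- ode_elastica(th, al, s)
    expect_lt(max(abs(sh$x_mm / 18 - od[, "x"])), 1e-6)
    expect_lt(max(abs(sh$y_mm / 18 - od[, "y"])), 1e-6)
    expect_equal(sh$theta[41], th, tolerance = 1e-7)
    # polyline arc length equals the leaflet length
    fine <- elastica_shape(sol, seq(0, 1, length.out = 2001))
    arc <- sum(sqrt(diff(fine$x_mm)^2 + diff(fine$y_mm)^2))
    expect_equal(arc / 18, 1, tolerance = 1e-6)
  }
})

test_that("shape starts at the origin and ends at the tip position", {
  sol <- solve_elastica(40 * deg, 5 * deg, 13, 500)
  sh <- elastica_shape(sol, c(0, 1))
  expect_equal(unname(unlist(sh[1, c("x_mm", "y_mm")])), c(0, 0))
  expect_equal(unname(unlist(sh[2, c("x_mm", "y_mm")])),
               unname(tip_position(sol)), tolerance = 1e-12)
})

test_that("unloaded and small-angle limits reduce to beam theory", {
  sol0 <- solve_elastica(0, 0.25, 18, 500)   # flat tip angle: no load
  expect_equal(sol0$P, 0, tolerance = 1e-15)
  expect_equal(unname(sol0$tip), c(18, 0))
  expect_equal(root_moment(sol0), 0, tolerance = 1e-12)
  # Euler-Bernoulli cantilever: tip deflection P l^3 / (3 B)
  for (th in c(0.5, 1, 2) * deg) {
    sol <- solve_elastica(th, 0, 18, 500)
    lin <- sol$P * 18^3 / (3 * 500)
    expect_equal(sol$tip[["y"]], lin, tolerance = 0.02)
  }
})

test_that("root moment equals the statics moment of the tip force", {
  set.seed(23)
  for (i in 1:10) {
    th <- runif(1, 10, 80) * deg
    al <- runif(1, 0, 50) * deg
    sol <- solve_elastica(th, al, 18, 500)
    # cross product of the tip position with the chordal pull
    Fv <- sol$P * c(-sin(al), cos(al))
    M_static <- abs(sol$tip[["x"]] * Fv[2] - sol$tip[["y"]] * Fv[1])
    expect_equal(root_moment(sol), M_static, tolerance = 1e-9)
    # and the finite-difference curvature of the tangent-angle field
    h <- 1e-5
    thetas <- elastica_shape(sol, c(0, h, 2 * h))$theta
    kappa0_fd <- (-3 * thetas[1] + 4 * thetas[2] - thetas[3]) / (2 * h) / 18
    expect_equal(root_moment(sol), 500 * kappa0_fd, tolerance = 1e-5)
  }
})

test_that("equilibrium field holds along the beam: B theta' = moment of tip force", {
  th <- 55 * deg; al <- 20 * deg; l <- 18; B <- 500
  sol <- solve_elastica(th, al, l, B)
  s <- seq(0, 1, length.out = 21)
  sh <- elastica_shape(sol, s)
  Fv <- sol$P * c(-sin(al), cos(al))
  b <- tip_position(sol)
  od <- ode_elastica(th, al, s)
  for (i in seq_along(s)) {
    arm <- c(b[["x"]] - sh$x_mm[i], b[["y"]] - sh$y_mm[i])
    M_s <- arm[1] * Fv[2] - arm[2] * Fv[1]
    expect_equal(unname(B * od[i, "thp"] / l), M_s, tolerance = 1e-6 * max(1, abs(M_s)))
  }
})

test_that("shape CSV export writes the documented columns", {
  sol <- solve_elastica(0.7, 0.1, 18, 500)
  path <- tempfile(fileext = ".csv")
  write_shape_csv(sol, path, n = 11)
  df <- read.csv(path)
  expect_identical(names(df), c("s", "x_mm", "y_mm"))
  expect_equal(nrow(df), 11)
  expect_equal(df$x_mm[11], sol$tip[["x"]], tolerance = 1e-6)
})
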