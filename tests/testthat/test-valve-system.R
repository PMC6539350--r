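# Two-leaflet assembly: papillary positions, congruency, equilibrium
# residuals, mirror symmetry.

deg <- pi / 180

test_that("papillary positions follow the chordal ray geometry", {
  expect_equal(pm_position_anterior(c(10, 5), 0, 45), c(10, 45))
  # tip on the annular plane: offset magnitude h tan(alpha), outboard
  m <- pm_position_anterior(c(10, 0), 20 * deg, 45)
  expect_equal(abs(m[1] - 10), 45 * tan(20 * deg))
  expect_equal(m[2], 45)
  expect_equal(pm_position_posterior(c(0, 5), 0, 30, 40), c(40, 30))
  expect_error(pm_position_anterior(c(10, 50), 0.1, 45), "above the leaflet")
  # trigonometric reconstruction at the reference geometry
  tip <- c(14.7, 9.4); al <- 25 * deg
  m <- pm_position_anterior(tip, al, 45)
  expect_equal(atan2(m[2] - tip[2], -(m[1] - tip[1])), pi / 2 - al,
               tolerance = 1e-12)
})

test_that("interpapillary distance is a symmetric Euclidean norm", {
  expect_equal(interpapillary_distance(c(3, 4), c(3, 4)), 0)
  expect_equal(interpapillary_distance(c(0, 30), c(7, 30)), 7)
  set.seed(41)
  for (i in 1:10) {
    a <- runif(2, -50, 50); b <- runif(2, -50, 50)
    expect_equal(interpapillary_distance(a, b),
                 sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2))
    expect_equal(interpapillary_distance(a, b), interpapillary_distance(b, a))
    expect_gte(interpapillary_distance(a, b) + 1e-12, abs(a[2] - b[2]))
  }
})

test_that("a configuration built from its own angles has zero congruency residual", {
  meas <- case_meas()
  set.seed(42)
  for (i in 1:6) {
    al <- runif(2, 5, 40) * deg
    th <- al + runif(2, 5, 35) * deg
    cfg <- build_configuration(th[1], th[2], al[1], al[2], meas)
    expect_lt(max(abs(chorda_congruency_residual(cfg))), 1e-12)
    # recomputing the chorda angles from the geometry returns the inputs
    va <- cfg$m_a - cfg$b_a
    vp <- cfg$m_p - cfg$b_p
    expect_equal(atan2(va[2], va[1]) - pi / 2, al[1], tolerance = 1e-9)
    expect_equal(pi / 2 - atan2(vp[2], vp[1]), al[2], tolerance = 1e-9)
  }
})

test_that("congruency residual shifts linearly with alpha and is translation invariant", {
  meas <- case_meas()
  cfg <- build_configuration(0.9, 1.2, 0.3, 0.35, meas)
  cfg2 <- cfg
  cfg2$alpha_a <- cfg$alpha_a + 1 * deg   # perturb alpha, hold the geometry
  r2 <- chorda_congruency_residual(cfg2)
  expect_equal(abs(r2[["anterior"]]), 1 * deg, tolerance = 1e-12)
  cfg3 <- cfg
  for (f in c("b_a", "b_p", "m_a", "m_p", "a_a", "a_p"))
    cfg3[[f]] <- cfg3[[f]] + c(12.3, 0)
  expect_equal(chorda_congruency_residual(cfg3),
               chorda_congruency_residual(cfg), tolerance = 1e-12)
})

test_that("node equilibrium residual vanishes only at the balanced stretch", {
  meas <- case_meas()
  mat <- meas$material
  cfg <- build_configuration(0.9, 1.2, 0.3, 0.35, meas)
  # unloaded, unstretched: zero residual by construction
  r0 <- node_equilibrium_residual(cfg, 0, 0,
                                  sqrt(sum((cfg$b_a - cfg$m_a)^2)),
                                  sqrt(sum((cfg$b_p - cfg$m_p)^2)), mat)
  expect_equal(unname(r0), c(0, 0))
  # residual changes sign around the equilibrium reference length
  P <- cfg$elastica_a$P
  lam_star <- equilibrium_stretch(P, mat)
  l_c <- sqrt(sum((cfg$b_a - cfg$m_a)^2))
  r_lo <- node_equilibrium_residual(cfg, P, 0, l_c / (lam_star * 0.95),
                                    l_c, mat)[["anterior"]]
  r_hi <- node_equilibrium_residual(cfg, P, 0, l_c / (lam_star * 1.05),
                                    l_c, mat)[["anterior"]]
  expect_lt(r_lo, 0)
  expect_gt(r_hi, 0)
  expect_lt(abs(node_equilibrium_residual(cfg, P, 0, l_c / lam_star, l_c,
                                          mat)[["anterior"]]), 1e-10 * mat$c1)
})

test_that("a symmetric valve is mirror symmetric about the midline", {
  meas <- valve_measurements(MAD_pre = 40, IPD_pre = 40, TH_pre = 9,
                             TH_opt = 5, delta_a = 40, delta_p = 40,
                             h_a = 35, h_p = 35, l_a = 16, l_p = 16)
  cfg <- build_configuration(0.9, 0.9, 0.3, 0.3, meas)
  mid <- meas$MAD_pre / 2
  expect_equal(cfg$b_a[1] - 0, meas$MAD_pre - cfg$b_p[1], tolerance = 1e-10)
  expect_equal(cfg$b_a[2], cfg$b_p[2], tolerance = 1e-10)
  expect_equal(mid - cfg$m_a[1], cfg$m_p[1] - mid, tolerance = 1e-10)
  # relabeling anterior/posterior leaves the interpapillary distance alone
  expect_equal(interpapillary_distance(cfg$m_a, cfg$m_p),
               interpapillary_distance(cfg$m_p, cfg$m_a))
})

test_that("measurement validation catches incompatible or implausible inputs", {
  expect_error(valve_measurements(delta_a = 120), "delta_a")
  expect_error(valve_measurements(TH_opt = 15), "TH_opt")
  expect_error(valve_measurements(MAD_pre = 4), "MAD_pre")
})
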