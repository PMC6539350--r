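# Postoperative scenario solves: residual contracts, constraint
# satisfaction, optimization contracts, indicators.

deg <- pi / 180

pre_case <- function(seed = 42)
  suppressWarnings(identify_preop(case_meas(), seed = seed))

test_that("solved optimized scenario satisfies every scaled residual", {
  pre <- pre_case()
  sol <- solve_scenario(pre, scenario = "optimized_pma", zeta = c(-0.8, -1.5))
  expect_lt(sol$residual_norm, 1e-8)
  res <- postop_residuals(sol$unknowns, pre, pre$measurements,
                          "optimized_pma", zeta = c(-0.8, -1.5))
  expect_lt(max(abs(res)), 1e-8)
  # coaptation and annular-width constraints
  expect_equal(sol$system$b_a[2], pre$measurements$TH_opt, tolerance = 1e-9)
  expect_equal(sol$system$b_p[2], pre$measurements$TH_opt, tolerance = 1e-9)
  expect_equal(sol$MAD_po, pre$measurements$MAD_pre - sol$surgical$r,
               tolerance = 1e-9)
  expect_equal(sol$system$b_a, sol$system$b_p, tolerance = 1e-9)
  # displaced papillary positions follow the orientation parameterization
  expect_equal(sol$system$m_a,
               pre$system$m_a + sol$surgical$u_a, tolerance = 1e-9)
  expect_equal(sol$surgical$u_a[2], -0.8 * sol$surgical$u_a[1],
               tolerance = 1e-9)
})

test_that("residual components respond locally to their own unknowns", {
  pre <- pre_case()
  sol <- solve_scenario(pre, scenario = "optimized_pma", zeta = c(-0.8, -1.5))
  u <- sol$unknowns
  # raising the coaptation target by 1 mm shifts exactly the two
  # tip-height residuals
  meas2 <- pre$measurements
  meas2$TH_opt <- meas2$TH_opt + 1
  r2 <- postop_residuals(u, pre, meas2, "optimized_pma", zeta = c(-0.8, -1.5))
  expect_equal(unname(r2[["coapt_a"]]), -1 / pre$measurements$MAD_pre,
               tolerance = 1e-9)
  expect_equal(unname(r2[["coapt_p"]]), -1 / pre$measurements$MAD_pre,
               tolerance = 1e-9)
  expect_lt(max(abs(r2[c("eq_a", "eq_p", "cong_a", "cong_p", "annulus")])),
            1e-8)
  # perturbing the anterior displacement leaves the posterior block alone
  u3 <- u; u3[["u_x_a"]] <- u3[["u_x_a"]] + 0.5
  r3 <- postop_residuals(u3, pre, pre$measurements, "optimized_pma",
                         zeta = c(-0.8, -1.5))
  expect_lt(max(abs(r3[c("eq_p", "cong_p", "coapt_a", "coapt_p")])), 1e-8)
  expect_gt(abs(r3[["cong_a"]]), 1e-4)
})

test_that("a symmetric preoperative state is a fixed point when the target is the preop height", {
  th <- 0.9; al <- 0.3
  tip <- tip_position(solve_elastica(th, al, 16, 500))
  meas <- valve_measurements(MAD_pre = 2 * tip[["x"]], IPD_pre = 30,
                             TH_pre = 9, TH_opt = 5, delta_a = 40,
                             delta_p = 40, h_a = 35, h_p = 35,
                             l_a = 16, l_p = 16)
  cfg <- build_configuration(th, th, al, al, meas)
  pre <- finalize_preop(cfg)
  meas2 <- meas
  meas2$TH_opt <- cfg$b_a[2]
  u <- c(theta_a = th, theta_p = th, alpha_a = al, alpha_p = al,
         u_x_a = 0, u_x_p = 0, r = meas$MAD_pre - cfg$b_a[1] - cfg$b_p_local[1])
  res <- postop_residuals(u, pre, meas2, "optimized_pma", zeta = c(0, 0))
  expect_lt(max(abs(res)), 1e-9)
})

test_that("invalid unknowns are flagged with large residuals, not errors", {
  pre <- pre_case()
  u <- c(theta_a = -0.5, theta_p = 0.9, alpha_a = 0.5, alpha_p = 0.3,
         u_x_a = 0, u_x_p = 0, r = 5)
  res <- postop_residuals(u, pre, pre$measurements, "optimized_pma")
  expect_true(all(is.finite(res)))
  expect_gte(max(abs(res)), 1e5)
})

test_that("annuloplasty-only solve balances fixed papillary muscles", {
  pre <- pre_case()
  sol <- solve_scenario(pre, scenario = "ra_only")
  expect_lt(sol$residual_norm, 1e-8)
  expect_equal(sol$system$m_a, pre$system$m_a)
  expect_equal(sol$system$m_p, pre$system$m_p)
  expect_equal(sol$system$b_a[2], pre$measurements$TH_opt, tolerance = 1e-9)
  expect_equal(sol$system$b_p[2], pre$measurements$TH_opt, tolerance = 1e-9)
  expect_equal(sol$surgical$r, sol$surgical$r_a + sol$surgical$r_p)
  # the per-side split leaves a reported tip abscissa gap diagnostic
  expect_true(is.finite(sol$tip_gap))
})

test_that("complete approximation honors an attainable prescribed distance", {
  meas <- mild_tethering_measurements()
  pre <- identify_preop(meas, mild_tethering_windows(), seed = 3)
  sol <- solve_scenario(pre, scenario = "complete_pma", ipd_target = 10,
                        ipd_mode = "strict")
  expect_lt(abs(sol$IPD_po - 10), 1e-8)
  expect_lt(sol$residual_norm, 1e-8)
  expect_equal(sol$surgical$zeta_a, sol$surgical$zeta_p)
  # unattainable prescription: strict mode reports the range, nearest clamps
  expect_error(solve_scenario(pre, scenario = "complete_pma",
                              ipd_target = 0.5, ipd_mode = "strict"),
               "attainable range")
  near <- solve_scenario(pre, scenario = "complete_pma", ipd_target = 0.5,
                         ipd_mode = "nearest")
  expect_true(near$surgical$ipd_clamped)
})

test_that("the orientation search returns the least-stress converged draw", {
  pre <- pre_case()
  best <- optimize_pma(pre, seed = 9, n_draws = 30)
  rec <- best$search
  expect_true(any(rec$converged))
  expect_lte(best$objective, min(rec$objective, na.rm = TRUE) + 1e-12)
  # the returned solution equals the plain scenario solve at its own draw
  direct <- solve_scenario(pre, scenario = "optimized_pma",
                           zeta = c(best$surgical$zeta_a,
                                    best$surgical$zeta_p))
  expect_equal(best$T_po, direct$T_po, tolerance = 1e-10)
  # enlarging the search never worsens the objective (nested draw sequences)
  more <- optimize_pma(pre, seed = 9, n_draws = 60)
  expect_lte(more$objective, best$objective + 1e-12)
})

test_that("indicators are unity at a null intervention and scale correctly", {
  pre <- pre_case()
  fake_post <- structure(list(
    scenario = "optimized_pma",
    M_po = pre$M_pre, T_po = pre$T_pre, lam_po = pre$lam_pre),
    class = "postop_configuration")
  ind <- indicators(pre, fake_post)
  expect_equal(unlist(ind[, c("Mr_a", "Mr_p", "Tr_a", "Tr_p", "lr_a", "lr_p")]),
               setNames(rep(1, 6), c("Mr_a", "Mr_p", "Tr_a", "Tr_p",
                                     "lr_a", "lr_p")))
  pre2 <- pre
  pre2$M_pre <- 2 * pre$M_pre
  ind2 <- indicators(pre2, fake_post)
  expect_equal(ind2$Mr_a, 0.5)
  pre3 <- pre
  pre3$M_pre[["a"]] <- 0
  expect_error(indicators(pre3, fake_post), "zero preoperative denominator")
})

test_that("scenario comparison shares the coaptation constraint across rows", {
  pre <- pre_case()
  cmp <- compare_scenarios(pre, seed = 13, n_draws = 25)
  expect_setequal(cmp$scenario, c("optimized_pma", "ra_only", "complete_pma"))
  sols <- attr(cmp, "solutions")
  for (s in sols) {
    expect_equal(s$system$b_a[2], pre$measurements$TH_opt, tolerance = 1e-8)
    expect_equal(s$system$b_p[2], pre$measurements$TH_opt, tolerance = 1e-8)
  }
})
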