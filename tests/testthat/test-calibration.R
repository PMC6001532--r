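# shared small-scale calibration fixtures (kept modest: the sweeps below
# run dozens of full imputation passes)
cal_data <- function(n = 4000, rho0 = FALSE, seed = 501) {
  simulate_pm(if (rho0) demo_pm_params_rho0() else demo_pm_params(),
              n, seed = seed)
}

test_that("with rho = 0 the achieved MSP sits on the identity line", {
  dat <- cal_data(rho0 = TRUE)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = 0))
  res <- calibrate_grid(dat, specs,
                        msp_specs = list(msp_spec("Y1"), msp_spec("Y2")),
                        test_values = list(Y1 = c(-3, -1.5, 0)),
                        m = 5, cycles = 5, seed = 11)
  expect_equal(nrow(res$grid), 3)
  expect_lt(max(abs(res$grid$msp_Y1 - res$grid$csp_Y1)), 0.2)
})

test_that("the CSP-to-MSP map is affine with unit slope on Gaussian data", {
  dat <- cal_data(n = 8000)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = -4.2))
  res <- calibrate_grid(dat, specs,
                        msp_specs = list(msp_spec("Y1")),
                        test_values = list(Y1 = seq(-4, 0, by = 1)),
                        m = 5, cycles = 5, seed = 12)
  line <- lm(msp_Y1 ~ csp_Y1, data = res$grid)
  expect_lt(abs(coef(line)[["csp_Y1"]] - 1), 0.12)
  expect_lt(max(abs(residuals(line))), 0.1)
  # achieved MSP responds monotonically to the CSP over the grid
  expect_true(all(diff(res$grid$msp_Y1[order(res$grid$csp_Y1)]) > -0.05))
})

test_that("elicited-range coverage is flagged and explained", {
  dat <- cal_data(n = 2000)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = -4.2))
  res <- calibrate_grid(dat, specs, msp_specs = list(msp_spec("Y1")),
                        test_values = list(Y1 = c(-1, 0)),
                        elicited_ranges = list(Y1 = c(-30, -25)),
                        m = 3, cycles = 3, seed = 13)
  expect_false(res$coverage[["Y1"]])
  expect_false(res$covered)
  expect_match(res$recommendation, "widen or recentre")
})

test_that("fixed-seed sweeps are bit-reproducible", {
  dat <- cal_data(n = 1500)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = 0))
  args <- list(dat, specs, msp_specs = list(msp_spec("Y1")),
               test_values = list(Y1 = c(-2, 0)), m = 3, cycles = 3,
               seed = 14)
  r1 <- do.call(calibrate_grid, args)
  r2 <- do.call(calibrate_grid, args)
  expect_identical(r1$grid, r2$grid)
})

test_that("one-at-a-time calibration brackets down to the analytic CSP", {
  p <- demo_pm_params()
  fc <- full_conditionals(p)
  dat <- simulate_pm(p, 20000, seed = 502)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = -2, Y2 = -3))
  res <- calibrate_one_at_a_time(dat, specs, msp_spec("Y1"), elicited = -2,
                                 initial_range = c(-5, 1), tolerance = 0.02,
                                 m = 5, cycles = 5, seed = 15)
  expect_true(res$converged)
  expect_lt(abs(res$calibrated - fc$Y1$csp), 0.2)
  expect_lt(abs(res$achieved_msp - (-2)), 0.1)
  # trace records every round's evaluations under the same seed
  expect_true(all(table(res$trace$round) >= 2))

  # rho = 0: calibrated CSP equals the elicited MSP
  dat0 <- simulate_pm(demo_pm_params_rho0(), 20000, seed = 503)
  specs0 <- make_narfcs_specs(dat0, csp = c(Y1 = -2, Y2 = -3))
  res0 <- calibrate_one_at_a_time(dat0, specs0, msp_spec("Y1"),
                                  elicited = -1,
                                  initial_range = c(-4, 2), tolerance = 0.02,
                                  m = 5, cycles = 5, seed = 16)
  expect_lt(abs(res0$calibrated - (-1)), 0.15)
})

test_that("an elicited value outside the achieved range demands a wider range", {
  dat <- cal_data(n = 1500)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = 0))
  expect_error(
    calibrate_one_at_a_time(dat, specs, msp_spec("Y1"), elicited = -40,
                            initial_range = c(-2, 0), tolerance = 0.05,
                            m = 3, cycles = 3, seed = 17),
    "widen the initial range")
})

test_that("joint calibration refines coarse grids to the analytic vector", {
  p <- demo_pm_params()
  fc <- full_conditionals(p)
  dat <- simulate_pm(p, 20000, seed = 504)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = -2, Y2 = -3))
  res <- calibrate_joint(dat, specs,
                         msp_specs = list(msp_spec("Y1"), msp_spec("Y2")),
                         elicited = c(Y1 = -2, Y2 = -3), tolerance = 0.1,
                         initial_values = list(Y1 = seq(-5, 1, by = 1.5),
                                               Y2 = seq(-7, -1, by = 1.5)),
                         n_test = 5, m = 4, cycles = 5, seed = 18,
                         max_rounds = 6)
  expect_true(res$converged)
  expect_lt(abs(res$primary$csp_Y1 - fc$Y1$csp), 0.4)
  expect_lt(abs(res$primary$csp_Y2 - fc$Y2$csp), 0.5)
  expect_true(all(abs(res$calibrated$msp_Y1 - (-2)) <= 0.1))
  expect_true(all(abs(res$calibrated$msp_Y2 - (-3)) <= 0.1))
})

test_that("the one-at-a-time check passes on Gaussian grids and demands a real grid", {
  dat <- cal_data(n = 4000)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = 0))
  res <- calibrate_grid(dat, specs,
                        msp_specs = list(msp_spec("Y1"), msp_spec("Y2")),
                        test_values = list(Y1 = c(-3, -1), Y2 = c(-5, -2)),
                        m = 4, cycles = 5, seed = 19)
  chk <- check_one_at_a_time(res, threshold = 0.3)
  expect_true(chk$pass)
  expect_true(all(chk$spread >= 0))
  # a zero threshold fails on any stochastic grid
  expect_false(check_one_at_a_time(res, threshold = 0)$pass)
  # a single-axis grid cannot support the check
  res1 <- calibrate_grid(dat, specs, msp_specs = list(msp_spec("Y1")),
                         test_values = list(Y1 = c(-2, 0)),
                         m = 2, cycles = 2, seed = 20)
  expect_error(check_one_at_a_time(res1), "at least two")
})

test_that("the generalised curve sweeps a user summary against the effect", {
  dat <- cal_data(n = 3000)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = 0, Y2 = -4.2))
  an <- analysis_spec(Y1 ~ 1, term = "(Intercept)")
  vals <- c(-4, -2, 0)
  cur <- generalized_curve(dat, specs, target = "Y1", csp_values = vals,
                           summary_fn = function(df) mean(df$Y1),
                           analysis = an, m = 3, cycles = 4, seed = 21)
  # the marginal-mean summary is affine in the CSP for gaussian models
  line <- lm(summary ~ csp_Y1, data = cur)
  expect_lt(max(abs(residuals(line))), 0.05)
  expect_gt(coef(line)[["csp_Y1"]], 0.1)
  # a constant summary gives a flat column
  flat <- generalized_curve(dat, specs, target = "Y1", csp_values = vals,
                            summary_fn = function(df) 42,
                            m = 2, cycles = 2, seed = 21)
  expect_equal(flat$summary, rep(42, 3))
  # the MSP-coefficient summary reproduces the calibration sweep
  msp_fn <- function(df) unname(coef(lm(Y1 ~ M_Y1, data = df))["M_Y1"])
  cur2 <- generalized_curve(dat, specs, target = "Y1", csp_values = vals,
                            summary_fn = msp_fn, m = 3, cycles = 4,
                            seed = 21)
  grid <- calibrate_grid(dat, specs, msp_specs = list(msp_spec("Y1")),
                         test_values = list(Y1 = vals),
                         m = 3, cycles = 4, seed = 21)
  expect_equal(cur2$summary, grid$grid$msp_Y1, tolerance = 1e-10)
})
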