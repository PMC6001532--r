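test_that("posterior draws agree with the closed-form least-squares posterior", {
  set.seed(202)
  n <- 10000
  x <- rnorm(n)
  y <- 2 + 3 * x + rnorm(n)
  X <- cbind(1, x)
  fit <- lm(y ~ x)
  post_mean <- coef(fit)
  post_sd <- sqrt(diag(vcov(fit)))
  for (s in 1:5) {
    set.seed(s)
    draw <- draw_linear_model(y, X)
    expect_lt(abs(draw$coef[1] - post_mean[1]), 4 * post_sd[1])
    expect_lt(abs(draw$coef[2] - post_mean[2]), 4 * post_sd[2])
    expect_lt(abs(draw$sigma - 1), 0.05)
  }
})

test_that("degenerate and invalid designs are handled", {
  # constant outcome, intercept-only: variance floor keeps the draw near it
  set.seed(7)
  draw <- draw_linear_model(rep(5, 30), matrix(1, 30, 1))
  expect_lt(abs(draw$coef[1] - 5), 1e-3)
  expect_lt(draw$sigma, 1e-3)
  # fewer observed rows than parameters
  expect_error(draw_linear_model(rnorm(3), matrix(rnorm(9), 3, 3)),
               "too few observed rows")
  # rank deficiency names the aliased term
  X <- cbind(a = rep(1, 20), b = rnorm(20))
  X <- cbind(X, c = X[, "b"])
  expect_error(draw_linear_model(rnorm(20), X), "aliased.*[bc]")
})

test_that("the CSP shifts the imputed predictive mean one-for-one", {
  set.seed(33)
  d <- data.frame(y = c(rnorm(4000, mean = 10), rep(NA, 1000)))
  inc <- incomplete_data(d)
  spec_shift <- narfcs_spec("y", csp = -5, vars = character(0))
  imp <- narfcs_impute(inc, list(spec_shift), m = 5, cycles = 2, seed = 9)
  imputed_means <- vapply(imp$completed, function(df)
    mean(df$y[inc$miss[, "y"]]), numeric(1))
  expect_lt(abs(mean(imputed_means) - (10 - 5)), 0.2)

  # offset linearity: same seed, delta 0 vs delta -3 differ by exactly -3
  spec0 <- narfcs_spec("y", csp = 0, vars = character(0))
  spec3 <- narfcs_spec("y", csp = -3, vars = character(0))
  i0 <- narfcs_impute(inc, list(spec0), m = 2, cycles = 3, seed = 17)
  i3 <- narfcs_impute(inc, list(spec3), m = 2, cycles = 3, seed = 17)
  expect_equal(i3$completed[[1]]$y[inc$miss[, "y"]],
               i0$completed[[1]]$y[inc$miss[, "y"]] - 3)
})

test_that("binomial family with zero logit imputes Bernoulli(0.5)", {
  set.seed(88)
  y <- rep(c(0, 1), each = 1500)
  y[sample(3000, 800)] <- NA
  inc <- incomplete_data(data.frame(y = y))
  spec <- narfcs_spec("y", csp = 0, family = "binomial", vars = character(0))
  imp <- narfcs_impute(inc, list(spec), m = 4, cycles = 2, seed = 10)
  imputed <- unlist(lapply(imp$completed, function(df) df$y[inc$miss[, "y"]]))
  expect_true(all(imputed %in% c(0, 1)))
  expect_lt(abs(mean(imputed) - 0.5), 0.06)
})

test_that("imputation is deterministic in the seed and preserves observed cells", {
  p <- demo_pm_params()
  dat <- simulate_pm(p, 500, seed = 41)
  specs <- make_narfcs_specs(dat, csp = c(Y1 = -2.3, Y2 = -4.2))
  a <- narfcs_impute(dat, specs, m = 3, cycles = 4, seed = 77)
  b <- narfcs_impute(dat, specs, m = 3, cycles = 4, seed = 77)
  expect_identical(a$completed, b$completed)
  c_ <- narfcs_impute(dat, specs, m = 3, cycles = 4, seed = 78)
  expect_false(identical(a$completed, c_$completed))
  for (i in 1:3) {
    got <- as.matrix(a$completed[[i]][, dat$var_names])
    expect_equal(got[!dat$miss], dat$values[!dat$miss])
  }
})

test_that("a complete dataset round-trips as m exact copies", {
  d <- data.frame(u = rnorm(40), v = rnorm(40))
  inc <- incomplete_data(d)
  imp <- narfcs_impute(inc, list(), m = 3, cycles = 2, seed = 1)
  for (i in 1:3)
    expect_equal(unname(as.matrix(imp$completed[[i]][, c("u", "v")])),
                 unname(inc$values))
})

test_that("with zero CSPs and no indicator terms the engine is exactly plain FCS", {
  set.seed(55)
  n <- 300
  d <- data.frame(y1 = rnorm(n), y2 = rnorm(n), x = rnorm(n))
  d$y1[sample(n, 60)] <- NA
  d$y2[sample(n, 80)] <- NA
  inc <- incomplete_data(d)
  specs <- make_narfcs_specs(inc, csp = c(y1 = 0, y2 = 0),
                             include_indicators = FALSE)
  imp <- narfcs_impute(inc, specs, m = 3, cycles = 5, seed = 123)
  oracle <- fcs_oracle(inc, targets = c("y1", "y2"),
                       predictors = list(y1 = c("y2", "x"),
                                         y2 = c("y1", "x")),
                       m = 3, cycles = 5, seed = 123)
  for (i in 1:3)
    expect_equal(unname(as.matrix(imp$completed[[i]][, inc$var_names])),
                 unname(oracle[[i]]))
})

test_that("spec validation catches coverage gaps and bad CSPs", {
  d <- data.frame(y1 = c(rnorm(30), rep(NA, 5)), y2 = c(NA, rnorm(34)))
  inc <- incomplete_data(d)
  s1 <- make_narfcs_specs(inc, csp = c(y1 = 0, y2 = 0))[[1]]
  expect_error(narfcs_impute(inc, list(s1), m = 2, cycles = 1, seed = 1),
               "cover exactly")
  expect_error(narfcs_spec("y1", csp = Inf), "finite")
  expect_error(make_narfcs_specs(inc, csp = c(y1 = 0, y2 = 0, zz = 1)),
               "complete or unknown")
})
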