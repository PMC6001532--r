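# shared fixtures, built in code

# the bivariate pattern-mixture parameter set used throughout the examples:
# strong correlation, unequal scales, moderate missingness
demo_pm_params <- function() {
  gaussian_pm_params(mu10 = 10, mu11 = -2, mu12 = 1,
                     mu20 = 20, mu21 = 1, mu22 = -3,
                     sigma1 = 2, sigma2 = 4, rho = 0.6,
                     pi1 = 0.3, pi2 = 0.25)
}

# uncorrelated variant: CSP and MSP coincide
demo_pm_params_rho0 <- function() {
  gaussian_pm_params(mu10 = 10, mu11 = -2, mu12 = 1,
                     mu20 = 20, mu21 = 1, mu22 = -3,
                     sigma1 = 2, sigma2 = 4, rho = 0,
                     pi1 = 0.3, pi2 = 0.25)
}

# small dataset with one incomplete outcome and complete covariates,
# y = b0 + b1*x1 + b2*x2 + noise, MCAR missingness on y
mcar_regression_data <- function(n = 800, miss = 0.25, seed = 301,
                                 beta = c(1, 2, -1), sd = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- beta[1] + beta[2] * x1 + beta[3] * x2 + rnorm(n, sd = sd)
  y[runif(n) < miss] <- NA
  incomplete_data(data.frame(y = y, x1 = x1, x2 = x2))
}

# independent transcription of the documented chained-equations contract
# (sub-seed derivation, initial fill, visit order, posterior-draw order),
# used as the bit-exact oracle for the plain-FCS reduction.  Written
# directly from the documented algorithm, not by calling engine internals.
fcs_oracle <- function(data, targets, predictors, m, cycles, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  seeds <- sample.int(2147483646L, m)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(seeds[i])
    V <- data$values
    for (t in targets) {
      mis <- data$miss[, t]
      V[mis, t] <- sample(V[!mis, t], sum(mis), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (t in targets) {
        mis <- data$miss[, t]
        X <- cbind(1, V[, predictors[[t]], drop = FALSE])
        obs <- !mis
        qrx <- qr(X[obs, , drop = FALSE])
        betahat <- qr.coef(qrx, V[obs, t])
        rss <- sum(qr.resid(qrx, V[obs, t])^2)
        sigma <- sqrt(max(rss / rchisq(1, sum(obs) - ncol(X)), 1e-10))
        z <- rnorm(ncol(X))
        beta <- betahat
        beta[qrx$pivot] <- beta[qrx$pivot] + sigma * drop(backsolve(qr.R(qrx), z))
        lp <- drop(X[mis, , drop = FALSE] %*% beta)
        V[mis, t] <- rnorm(sum(mis), lp, sigma)
      }
    }
    out[[i]] <- V
  }
  out
}
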