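#' Pool per-imputation estimates by Rubin's rules
#'
#' Combines m point estimates and their squared standard errors into a
#' pooled estimate with total variance T = W + (1 + 1/m) B, where W is the
#' mean within-imputation variance and B the between-imputation (sample)
#' variance of the estimates.  Degrees of freedom use the Barnard-Rubin
#' small-sample adjustment when a finite complete-data df is supplied.
#'
#' @param estimates numeric vector of per-imputation estimates (m >= 2).
#' @param variances per-imputation squared standard errors, all positive.
#' @param complete_df complete-data degrees of freedom (`Inf` for the
#'   large-sample formula).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A `pooled_estimate` object: list with `estimate`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `ci_low`, `ci_high`,
#'   `p_value`, `m`.
#' @examples
#' pool_rubin(c(1.0, 1.2, 1.4), rep(0.04, 3), complete_df = 100)
#' @export
pool_rubin <- function(estimates, variances, complete_df = Inf,
                       conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("pooling needs m >= 2 (between-imputation variance undefined)")
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("variances must be positive and finite")
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t_var <- w + (1 + 1/m) * b
  lambda <- (1 + 1/m) * b / t_var
  if (lambda < 1e-12) {
    df <- if (is.finite(complete_df)) complete_df else 1e8
  } else {
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(complete_df)) {
      df_obs <- (complete_df + 1) / (complete_df + 3) * complete_df * (1 - lambda)
      df_old * df_obs / (df_old + df_obs)
    } else df_old
  }
  se <- sqrt(t_var)
  alpha <- 1 - conf_level
  tcrit <- stats::qt(1 - alpha / 2, df)
  p <- 2 * stats::pt(-abs(qbar / se), df)
  structure(list(estimate = qbar, within_var = w, between_var = b,
                 total_var = t_var, se = se, df = df,
                 ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
                 p_value = p, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.5g (se %.4g, df %.1f, 95%% CI [%.5g, %.5g], p = %.3g)\n",
              x$estimate, x$se, x$df, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Fit a regression on each completed dataset and pool coefficient-wise
#'
#' Fits `formula` by [stats::lm()] (gaussian) or [stats::glm()] (binomial)
#' on each of the m completed datasets of an imputation run — the
#' indicator columns `M_<var>` are available as regressors, so marginal
#' sensitivity-parameter (MSP) models like `y ~ M_y` can be fitted
#' directly — and pools each coefficient by [pool_rubin()] with
#' complete-data df n - p.
#'
#' @param imp a `narfcs_imp` object.
#' @param formula model formula in the dataset's variables / indicators.
#' @param family `"gaussian"` or `"binomial"`.
#' @param conf_level confidence level (default 0.95).
#' @return Data frame, one row per coefficient: `term`, `estimate`, `se`,
#'   `df`, `ci_low`, `ci_high`, `p_value`, plus `within_var` and
#'   `between_var` columns.
#' @export
pooled_fit <- function(imp, formula, family = "gaussian", conf_level = 0.95) {
  stopifnot(inherits(imp, "narfcs_imp"))
  ests <- vars <- NULL
  cdf <- NA_real_
  for (i in seq_len(imp$m)) {
    df_i <- imp$completed[[i]]
    fit <- if (family == "gaussian") stats::lm(formula, data = df_i)
           else stats::glm(formula, data = df_i, family = stats::binomial())
    co <- stats::coef(fit)
    if (anyNA(co))
      stop("singular fit in imputation ", i, ": aliased terms ",
           paste(names(co)[is.na(co)], collapse = ", "))
    vc <- diag(stats::vcov(fit))
    if (is.null(ests)) {
      ests <- matrix(NA_real_, imp$m, length(co), dimnames = list(NULL, names(co)))
      vars <- ests
      cdf <- stats::nobs(fit) - length(co)
    }
    ests[i, ] <- co
    vars[i, ] <- vc
  }
  rows <- lapply(colnames(ests), function(term) {
    p <- pool_rubin(ests[, term], vars[, term], complete_df = cdf,
                    conf_level = conf_level)
    data.frame(term = term, estimate = p$estimate, se = p$se, df = p$df,
               ci_low = p$ci_low, ci_high = p$ci_high, p_value = p$p_value,
               within_var = p$within_var, between_var = p$between_var,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
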