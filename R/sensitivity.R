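#' Tipping-point analysis over a CSP grid
#'
#' Sweeps the Cartesian grid of CSP values (fixed-seed imputation at each
#' vector, as in [calibrate_grid()]), records the pooled effect of
#' interest with its confidence interval and p-value, and reports, per
#' varied axis, the first grid value (moving away from the cell nearest
#' zero, with the other axes held at that reference cell) at which the
#' significance status at level `alpha` flips — the tipping point.  When
#' MSP models are supplied the tipping CSPs are also mapped to their
#' achieved MSPs, which are the interpretable scale on which to judge
#' plausibility.
#'
#' @param data,specs,analysis,m,cycles,seed as in [calibrate_grid()].
#' @param csp_grids named list of regularly spaced CSP values, one entry
#'   per varied variable.
#' @param alpha significance level (default 0.05).
#' @param msp_specs optional list of [msp_spec()] used to map tipping
#'   CSPs to MSPs.
#' @return A `tipping_result`: `grid` (the p-value surface in long
#'   format, ready for contour plotting), `tipping` (data frame: variable,
#'   tipping CSP, mapped MSP if available), `alpha`, `reference` (the
#'   near-zero cell), and `flagged` (axes where no tipping is detectable).
#' @export
tipping_point <- function(data, specs, analysis, csp_grids, alpha = 0.05,
                          msp_specs = list(), m = 10, cycles = 10, seed) {
  stopifnot(inherits(analysis, "analysis_spec"), alpha > 0, alpha < 1)
  grid <- expand.grid(csp_grids, KEEP.OUT.ATTRS = FALSE)
  tab <- .sweep_grid(data, specs, grid, msp_specs, analysis, NULL,
                     m, cycles, seed)
  vars <- names(csp_grids)
  csp_cols <- paste0("csp_", vars)
  # reference cell: closest to the all-zero CSP vector
  ref_i <- which.min(rowSums(abs(as.matrix(tab[csp_cols]))))
  ref <- tab[ref_i, csp_cols, drop = FALSE]
  ref_sig <- tab$effect_p[ref_i] < alpha
  tipping <- list()
  flagged <- character(0)
  for (v in vars) {
    if (length(unique(csp_grids[[v]])) < 2L) {
      flagged <- c(flagged, sprintf(
        "axis '%s' has a single grid value; no tipping detectable", v))
      next
    }
    others <- setdiff(csp_cols, paste0("csp_", v))
    on_axis <- rep(TRUE, nrow(tab))
    for (oc in others) on_axis <- on_axis & tab[[oc]] == ref[[oc]]
    axis_tab <- tab[on_axis, ]
    axis_tab <- axis_tab[order(abs(axis_tab[[paste0("csp_", v)]])), ]
    flip <- which((axis_tab$effect_p < alpha) != ref_sig)
    if (length(flip)) {
      row <- axis_tab[flip[1], ]
      tipping[[v]] <- data.frame(
        variable = v, csp = row[[paste0("csp_", v)]],
        msp = if (paste0("msp_", v) %in% names(row))
          row[[paste0("msp_", v)]] else NA_real_,
        effect = row$effect, p_value = row$effect_p)
    }
  }
  structure(list(grid = tab,
                 tipping = if (length(tipping)) do.call(rbind, tipping)
                           else NULL,
                 alpha = alpha, reference = ref, reference_sig = ref_sig,
                 flagged = flagged, seed = seed),
            class = "tipping_result")
}

#' @export
print.tipping_result <- function(x, ...) {
  cat("Tipping-point analysis (alpha =", x$alpha, ")\n")
  cat("  reference cell significant:", x$reference_sig, "\n")
  if (is.null(x$tipping)) {
    cat("  no tipping point found on any varied axis\n")
  } else {
    for (i in seq_len(nrow(x$tipping)))
      cat(sprintf("  %s: tipping CSP %.4g (MSP %.4g), p = %.3g\n",
                  x$tipping$variable[i], x$tipping$csp[i], x$tipping$msp[i],
                  x$tipping$p_value[i]))
  }
  for (f in x$flagged) cat("  note:", f, "\n")
  invisible(x)
}

#' Monte Carlo performance metrics for one estimator
#'
#' Bias (mean estimate minus truth), empirical SE (SD of the estimates
#' across replicates), percentage coverage of the supplied confidence
#' intervals, and the corresponding Monte Carlo errors: bias MCE =
#' empSE/sqrt(R), empSE MCE = empSE/sqrt(2(R-1)), coverage MCE =
#' 100*sqrt(p(1-p)/R).
#'
#' @param estimates,ci_lows,ci_highs equal-length numeric vectors over
#'   replicates.
#' @param truth the true parameter value.
#' @return One-row data frame: `true_value`, `bias`, `empirical_se`,
#'   `coverage_pct`, `mc_error_bias`, `mc_error_se`, `mc_error_coverage`,
#'   `n_reps`, `degenerate` (TRUE when fewer than 2 replicates make the
#'   SE undefined).
#' @export
compute_metrics <- function(estimates, ci_lows, ci_highs, truth) {
  R <- length(estimates)
  stopifnot(length(ci_lows) == R, length(ci_highs) == R, R >= 1L)
  bias <- mean(estimates) - truth
  covered <- ci_lows <= truth & truth <= ci_highs
  p_hat <- mean(covered)
  if (R >= 2L) {
    emp_se <- stats::sd(estimates)
    mce_bias <- emp_se / sqrt(R)
    mce_se <- emp_se / sqrt(2 * (R - 1))
    degenerate <- FALSE
  } else {
    emp_se <- mce_bias <- mce_se <- NA_real_
    degenerate <- TRUE
  }
  data.frame(true_value = truth, bias = bias, empirical_se = emp_se,
             coverage_pct = 100 * p_hat,
             mc_error_bias = mce_bias, mc_error_se = mce_se,
             mc_error_coverage = 100 * sqrt(p_hat * (1 - p_hat) / R),
             n_reps = R, degenerate = degenerate)
}

#' Monte Carlo simulation study of NARFCS sensitivity-parameter misuse
#'
#' Simulates `n_reps` replicate datasets from the Gaussian pattern-mixture
#' process and, per replicate, imputes under up to three arms of the
#' NARFCS models (all with both cross-indicator terms):
#' \describe{
#'   \item{`true_csps`}{the analytically exact CSPs from
#'     [full_conditionals()] — the unattainable benchmark;}
#'   \item{`insert_msps`}{the MSPs inserted directly as if they were CSPs
#'     — the misuse the calibration machinery exists to prevent;}
#'   \item{`calibrated`}{CSPs calibrated once by
#'     [calibrate_one_at_a_time()] on a large auxiliary dataset from the
#'     same process (elicited values = the true MSPs, other CSPs fixed at
#'     the elicited MSPs), then reused for every replicate; set
#'     `calibrate_per_replicate = TRUE` to recalibrate on each replicate
#'     instead.}
#' }
#' Each arm's intercept-only models for Y1 and Y2 are pooled by Rubin's
#' rules and the pooled estimates and 95% CIs are scored against the
#' analytic marginal means with [compute_metrics()].
#'
#' @param params a [gaussian_pm_params()] object.
#' @param n subjects per replicate.
#' @param n_reps number of replicates.
#' @param methods subset of `c("true_csps", "insert_msps", "calibrated")`.
#' @param m,cycles imputation settings per replicate.
#' @param seed master seed; sub-streams drive the calibration dataset,
#'   each replicate's data, and each arm's imputation.
#' @param calibration_n size of the auxiliary calibration dataset.
#' @param calibration_tolerance Algorithm-3 tolerance on the MSP scale.
#' @param calibration_range_halfwidth half-width of the initial CSP search
#'   range, centred on the elicited MSP.
#' @param calibrate_per_replicate recalibrate on every replicate (much
#'   costlier; default FALSE).
#' @return A `simulation_metrics` object: `metrics` (data frame, one row
#'   per method x parameter with Table-style columns), `max_mc_error`
#'   (largest bias/SE MCEs over reported cells and the worst-case p = 0.5
#'   coverage MCE), `csps` (CSP vectors used per arm), `estimates`,
#'   `failures`.
#' @export
run_simulation_study <- function(params, n = 1000, n_reps = 1000,
                                 methods = c("true_csps", "insert_msps",
                                             "calibrated"),
                                 m = 10, cycles = 10, seed,
                                 calibration_n = 100000,
                                 calibration_tolerance = 0.01,
                                 calibration_range_halfwidth = 3,
                                 calibrate_per_replicate = FALSE) {
  stopifnot(inherits(params, "gaussian_pm_params"))
  methods <- match.arg(methods, several.ok = TRUE)
  truth <- marginal_means(params)
  cond <- full_conditionals(params)
  true_csps <- c(Y1 = cond$Y1$csp, Y2 = cond$Y2$csp)
  msps <- c(Y1 = cond$Y1$msp, Y2 = cond$Y2$msp)
  top_seeds <- .derive_seeds(seed, 2L)
  msp_specs <- list(Y1 = msp_spec("Y1"), Y2 = msp_spec("Y2"))

  calibrate_on <- function(dat, cal_seed) {
    specs <- make_narfcs_specs(dat, csp = msps)
    vapply(c("Y1", "Y2"), function(v) {
      calibrate_one_at_a_time(
        dat, specs, msp_specs[[v]], elicited = msps[[v]],
        initial_range = msps[[v]] + c(-1, 1) * calibration_range_halfwidth,
        tolerance = calibration_tolerance, m = m, cycles = cycles,
        seed = cal_seed)$calibrated
    }, numeric(1))
  }

  arm_csps <- list()
  if ("true_csps" %in% methods) arm_csps$true_csps <- true_csps
  if ("insert_msps" %in% methods) arm_csps$insert_msps <- msps
  if ("calibrated" %in% methods && !calibrate_per_replicate) {
    cal_data <- simulate_pm(params, calibration_n, top_seeds[1])
    arm_csps$calibrated <- calibrate_on(cal_data, top_seeds[1])
  }

  rep_seeds <- .derive_seeds(top_seeds[2], n_reps)
  est <- array(NA_real_, c(n_reps, length(methods), 2L),
               dimnames = list(NULL, methods, c("Y1", "Y2")))
  lo <- hi <- est
  failures <- 0L
  for (r in seq_len(n_reps)) {
    sub <- .derive_seeds(rep_seeds[r], 1L + length(methods))
    dat <- simulate_pm(params, n, sub[1])
    if (calibrate_per_replicate && "calibrated" %in% methods)
      arm_csps$calibrated <- calibrate_on(dat, sub[1])
    for (a in seq_along(methods)) {
      arm <- methods[a]
      res <- tryCatch({
        specs <- make_narfcs_specs(dat, csp = arm_csps[[arm]])
        imp <- narfcs_impute(dat, specs, m = m, cycles = cycles,
                             seed = sub[1L + a])
        lapply(c(Y1 = "Y1", Y2 = "Y2"), function(v) {
          pooled_fit(imp, stats::as.formula(paste(v, "~ 1")))
        })
      }, error = function(e) e)
      if (inherits(res, "error")) { failures <- failures + 1L; next }
      for (v in c("Y1", "Y2")) {
        row <- res[[v]]
        est[r, arm, v] <- row$estimate
        lo[r, arm, v] <- row$ci_low
        hi[r, arm, v] <- row$ci_high
      }
    }
  }
  if (failures > 0.01 * n_reps * length(methods))
    warning(failures, " replicate-arm failures (> 1%) were excluded")

  rows <- list()
  for (arm in methods) for (v in c("Y1", "Y2")) {
    keep <- !is.na(est[, arm, v])
    met <- compute_metrics(est[keep, arm, v], lo[keep, arm, v],
                           hi[keep, arm, v], truth[[v]])
    rows[[paste(arm, v)]] <- cbind(method = arm, parameter = v, met)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  max_mc <- c(bias = max(metrics$mc_error_bias, na.rm = TRUE),
              se = max(metrics$mc_error_se, na.rm = TRUE),
              coverage = 100 * sqrt(0.25 / min(metrics$n_reps)))
  structure(list(metrics = metrics, max_mc_error = max_mc,
                 csps = arm_csps, truth = truth,
                 estimates = list(est = est, ci_low = lo, ci_high = hi),
                 failures = failures, n = n, n_reps = n_reps, m = m,
                 cycles = cycles, seed = seed),
            class = "simulation_metrics")
}

#' @export
print.simulation_metrics <- function(x, digits = 3, ...) {
  cat("Simulation study:", x$n_reps, "replicates, n =", x$n,
      ", m =", x$m, ", cycles =", x$cycles, "\n")
  tab <- x$metrics[, c("method", "parameter", "true_value", "bias",
                       "empirical_se", "coverage_pct")]
  names(tab) <- c("Method", "Parameter", "True Value", "Bias",
                  "Empirical SE", "Coverage, 95%")
  print(format(tab, digits = digits), row.names = FALSE)
  cat(sprintf("Max MC error: bias %.3f, SE %.3f, coverage %.3f\n",
              x$max_mc_error[["bias"]], x$max_mc_error[["se"]],
              x$max_mc_error[["coverage"]]))
  invisible(x)
}
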