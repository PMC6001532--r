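#' Specify a marginal-sensitivity-parameter (MSP) model
#'
#' A pattern-mixture regression of an incomplete variable on its own
#' missingness indicator, optionally conditioning on further terms.  With
#' no conditioning terms this is the fully marginal form
#' `outcome ~ M_outcome`, whose indicator coefficient is the mean
#' difference between imputed and observed values of the outcome —
#' the elicitable MSP.
#'
#' @param outcome name of the incomplete variable.
#' @param conditioning character vector of additional regressors (must
#'   not include the outcome); empty for the fully marginal model.
#' @return An `msp_spec` object with the model `formula` and the name of
#'   the `msp_term` (the outcome's indicator).
#' @export
msp_spec <- function(outcome, conditioning = character(0)) {
  if (outcome %in% conditioning)
    stop("conditioning terms must exclude the outcome")
  msp_term <- paste0("M_", outcome)
  rhs <- paste(c(conditioning, sprintf("`%s`", msp_term)), collapse = " + ")
  structure(list(outcome = outcome, conditioning = conditioning,
                 msp_term = msp_term,
                 formula = stats::as.formula(paste(outcome, "~", rhs))),
            class = "msp_spec")
}

#' Specify the substantive analysis model
#'
#' @param formula model formula fitted to each completed dataset.
#' @param term coefficient of interest (default the first non-intercept
#'   term; `"(Intercept)"` for intercept-only models).
#' @param family `"gaussian"` or `"binomial"`.
#' @return An `analysis_spec` object.
#' @export
analysis_spec <- function(formula, term = NULL, family = "gaussian") {
  if (is.null(term)) {
    labs <- attr(stats::terms(formula), "term.labels")
    term <- if (length(labs)) labs[1] else "(Intercept)"
  }
  structure(list(formula = formula, term = term, family = family),
            class = "analysis_spec")
}

# set CSP values (named vector) into a list of narfcs_spec objects
.set_csps <- function(specs, csp) {
  for (k in seq_along(specs)) {
    t <- specs[[k]]$target
    if (t %in% names(csp)) specs[[k]]$csp <- csp[[t]]
  }
  specs
}

# impute at one CSP vector (fixed seed) and measure: pooled MSP estimate
# per msp_spec, pooled analysis effect, optional user summary
.impute_and_measure <- function(data, specs, csp, msp_specs, analysis,
                                summary_fn, m, cycles, seed) {
  imp <- narfcs_impute(data, .set_csps(specs, csp), m = m, cycles = cycles,
                       seed = seed)
  out <- list()
  if (length(msp_specs)) {
    out$msp <- vapply(msp_specs, function(ms) {
      tab <- pooled_fit(imp, ms$formula, family = "gaussian")
      tab$estimate[tab$term == sprintf("`%s`", ms$msp_term) |
                   tab$term == ms$msp_term]
    }, numeric(1))
    names(out$msp) <- vapply(msp_specs, `[[`, character(1), "outcome")
  }
  if (!is.null(analysis)) {
    tab <- pooled_fit(imp, analysis$formula, family = analysis$family)
    row <- tab[tab$term == analysis$term, ]
    if (nrow(row) != 1L)
      stop("analysis term '", analysis$term, "' not found in fitted model")
    out$effect <- row
  }
  if (!is.null(summary_fn)) {
    out$summary <- mean(vapply(imp$completed, summary_fn, numeric(1)))
  }
  out
}

# sweep a CSP grid (data.frame, one column per incomplete variable being
# varied) with the same seed at every point; failed points are recorded
# and skipped
.sweep_grid <- function(data, specs, grid, msp_specs = list(),
                        analysis = NULL, summary_fn = NULL,
                        m, cycles, seed) {
  res <- vector("list", nrow(grid))
  errors <- character(0)
  for (g in seq_len(nrow(grid))) {
    csp <- unlist(grid[g, , drop = FALSE])
    meas <- tryCatch(
      .impute_and_measure(data, specs, csp, msp_specs, analysis,
                          summary_fn, m, cycles, seed),
      error = function(e) e)
    if (inherits(meas, "error")) {
      errors <- c(errors, sprintf("grid point %d (%s): %s", g,
                                  paste(sprintf("%s=%.4g", names(csp), csp),
                                        collapse = ", "),
                                  conditionMessage(meas)))
      next
    }
    row <- as.data.frame(as.list(stats::setNames(csp, paste0("csp_", names(csp)))))
    if (!is.null(meas$msp))
      row <- cbind(row, as.data.frame(as.list(
        stats::setNames(meas$msp, paste0("msp_", names(meas$msp))))))
    if (!is.null(meas$effect))
      row <- cbind(row, effect = meas$effect$estimate,
                   effect_ci_low = meas$effect$ci_low,
                   effect_ci_high = meas$effect$ci_high,
                   effect_p = meas$effect$p_value)
    if (!is.null(meas$summary)) row <- cbind(row, summary = meas$summary)
    res[[g]] <- row
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  attr(out, "errors") <- errors
  out
}

#' Calibration sweep over a grid of CSP test vectors (Algorithm 1)
#'
#' For every combination of the supplied CSP test values the data are
#' imputed with a fixed seed, the MSP models are fitted by pooled
#' regression to estimate the achieved MSPs, and (optionally) the
#' substantive effect of interest is estimated from the same imputed
#' data.  The result records whether the achieved MSP range of each
#' variable covers its elicited range; sensitivity analysis then tabulates
#' or plots the effect against the achieved MSPs.
#'
#' @param data an [incomplete_data()] object.
#' @param specs NARFCS model specs ([make_narfcs_specs()]).
#' @param msp_specs list of [msp_spec()], one per calibrated variable.
#' @param test_values named list: for each calibrated variable, the
#'   regularly spaced CSP test values (at most ~10 recommended — the grid
#'   is the Cartesian product).
#' @param elicited_ranges optional named list of `c(low, high)` elicited
#'   MSP ranges, used for the coverage check.
#' @param analysis optional [analysis_spec()] for the effect of interest.
#' @param m,cycles,seed imputation settings; the same `seed` is reused at
#'   every grid point so the sweep is a deterministic function of the CSPs.
#' @return A `calibration_result` with the `grid` table (columns
#'   `csp_<v>`, `msp_<v>`, and effect columns), per-variable `coverage`
#'   flags, and a `recommendation` when coverage fails (widen or recentre
#'   the test range).
#' @export
calibrate_grid <- function(data, specs, msp_specs, test_values,
                           elicited_ranges = NULL, analysis = NULL,
                           m = 10, cycles = 10, seed) {
  stopifnot(all(lengths(test_values) >= 1L))
  grid <- expand.grid(test_values, KEEP.OUT.ATTRS = FALSE)
  tab <- .sweep_grid(data, specs, grid, msp_specs, analysis,
                     NULL, m, cycles, seed)
  coverage <- NULL
  recommendation <- character(0)
  if (!is.null(elicited_ranges)) {
    coverage <- vapply(names(elicited_ranges), function(v) {
      ach <- range(tab[[paste0("msp_", v)]])
      el <- range(elicited_ranges[[v]])
      ach[1] <= el[1] && ach[2] >= el[2]
    }, logical(1))
    for (v in names(coverage)[!coverage])
      recommendation <- c(recommendation, sprintf(
        "achieved MSP range for '%s' [%.4g, %.4g] does not cover the elicited range [%.4g, %.4g]; widen or recentre its CSP test range",
        v, min(tab[[paste0("msp_", v)]]), max(tab[[paste0("msp_", v)]]),
        min(elicited_ranges[[v]]), max(elicited_ranges[[v]])))
  }
  structure(list(grid = tab, coverage = coverage,
                 covered = is.null(coverage) || all(coverage),
                 elicited_ranges = elicited_ranges,
                 recommendation = recommendation,
                 errors = attr(tab, "errors"), seed = seed,
                 m = m, cycles = cycles),
            class = "calibration_result")
}

#' Joint calibration of all CSPs for point-elicited MSPs (Algorithm 2)
#'
#' Repeated grid sweeps, coarse to fine: each round runs
#' [calibrate_grid()] on the current test values, looks for test vectors
#' whose achieved MSPs all lie within tolerance of the elicited values,
#' and otherwise shrinks each variable's range to the two test values
#' whose achieved MSPs bracket (or come closest to) its elicited value.
#' Several vectors can qualify; all are returned, with the one minimising
#' the maximum tolerance-standardised deviation designated primary.
#'
#' @param data,specs,msp_specs,analysis,m,cycles,seed as in
#'   [calibrate_grid()].
#' @param elicited named numeric vector of elicited MSP values.
#' @param tolerance per-MSP tolerance (scalar recycled; default 0.001).
#' @param initial_values named list of initial CSP test values.
#' @param n_test test values per variable in refinement rounds.
#' @param max_rounds maximum refinement rounds (default 10); an
#'   unconverged result is flagged, with the nearest vector reported.
#' @return A `calibration_result` with `calibrated` (data frame of
#'   qualifying CSP vectors and achieved MSPs), `primary`, `converged`,
#'   `rounds`, and the accumulated `grid` (with a `round` column).
#' @export
calibrate_joint <- function(data, specs, msp_specs, elicited,
                            tolerance = 0.001, initial_values,
                            n_test = 10, analysis = NULL,
                            m = 10, cycles = 10, seed, max_rounds = 10) {
  vars <- names(elicited)
  stopifnot(length(vars) == length(msp_specs), all(tolerance > 0))
  tol <- stats::setNames(rep_len(tolerance, length(vars)), vars)
  test_values <- initial_values[vars]
  all_grids <- list()
  for (round in seq_len(max_rounds)) {
    grid <- expand.grid(test_values, KEEP.OUT.ATTRS = FALSE)
    tab <- .sweep_grid(data, specs, grid, msp_specs, analysis, NULL,
                       m, cycles, seed)
    all_grids[[round]] <- cbind(round = round, tab)
    dev <- sapply(vars, function(v) abs(tab[[paste0("msp_", v)]] - elicited[[v]]))
    dev <- matrix(dev, nrow = nrow(tab), dimnames = list(NULL, vars))
    std <- sweep(dev, 2, tol[vars], "/")
    ok <- rowSums(std <= 1) == length(vars)
    if (any(ok)) {
      qual <- tab[ok, , drop = FALSE]
      primary <- qual[which.min(apply(std[ok, , drop = FALSE], 1, max)), ,
                      drop = FALSE]
      return(structure(list(
        calibrated = qual, primary = primary, converged = TRUE,
        rounds = round, grid = do.call(rbind, all_grids),
        elicited = elicited, tolerance = tol, seed = seed),
        class = "calibration_result"))
    }
    # shrink each variable's range around its bracketing test values
    test_values <- lapply(stats::setNames(vars, vars), function(v) {
      msp_v <- tab[[paste0("msp_", v)]]
      csp_v <- tab[[paste0("csp_", v)]]
      lo <- csp_v[msp_v <= elicited[[v]]]
      hi <- csp_v[msp_v >= elicited[[v]]]
      lo <- if (length(lo)) max(lo) else min(csp_v)
      hi <- if (length(hi)) min(hi) else max(csp_v)
      if (lo == hi) {  # degenerate bracket: widen by one grid step
        step <- if (length(unique(csp_v)) > 1L)
          min(diff(sort(unique(csp_v)))) else max(abs(lo), 1) * 0.1
        lo <- lo - step; hi <- hi + step
      }
      seq(min(lo, hi), max(lo, hi), length.out = n_test)
    })
  }
  full_grid <- do.call(rbind, all_grids)
  dev_all <- sapply(vars, function(v)
    abs(full_grid[[paste0("msp_", v)]] - elicited[[v]]) / tol[[v]])
  nearest <- full_grid[which.min(apply(matrix(dev_all, nrow = nrow(full_grid)),
                                       1, max)), , drop = FALSE]
  structure(list(calibrated = nearest[0, ], primary = nearest,
                 converged = FALSE, rounds = max_rounds, grid = full_grid,
                 elicited = elicited, tolerance = tol, seed = seed),
            class = "calibration_result")
}

#' One-at-a-time CSP calibration by bracketing search (Algorithm 3)
#'
#' Calibrates the CSP of a single variable to a point-elicited MSP while
#' the other variables' CSPs stay fixed (sensible fixed values are their
#' own elicited MSPs).  Each round evaluates the achieved MSP at regularly
#' spaced test values of the target CSP (same seed every evaluation),
#' brackets the elicited value between the two nearest achieved MSPs, and
#' re-grids inside the bracket; the search stops when the two bracketing
#' achieved MSPs agree to within `tolerance`, returning the test value
#' whose achieved MSP is closest to the elicited value.  Valid when the
#' CSP-MSP relationship of one variable does not depend on the other
#' CSPs (the one-at-a-time assumption; see [check_one_at_a_time()]).
#'
#' @param data,specs,m,cycles,seed as in [calibrate_grid()].
#' @param msp_spec the target variable's [msp_spec()].
#' @param elicited the elicited MSP value.
#' @param initial_range `c(low, high)` initial CSP range; should be wide
#'   (an error asks for a wider range if the elicited value falls outside
#'   the achieved MSP range of the first sweep).
#' @param fixed_csps named CSP values for the other incomplete variables
#'   (default: the values already in `specs`).
#' @param tolerance convergence tolerance on the MSP scale (default 0.001).
#' @param n_test test values per round (default 10).
#' @param max_rounds refinement-round cap (default 10); unconverged
#'   results are returned flagged, never silently.
#' @return A `calibration_result` with scalar `calibrated` CSP,
#'   `achieved_msp`, `converged`, `rounds`, and the full `trace` of
#'   (round, csp, achieved msp) evaluations.
#' @export
calibrate_one_at_a_time <- function(data, specs, msp_spec, elicited,
                                    initial_range, fixed_csps = NULL,
                                    tolerance = 0.001, n_test = 10,
                                    m = 10, cycles = 10, seed,
                                    max_rounds = 10) {
  stopifnot(inherits(msp_spec, "msp_spec"), length(initial_range) == 2L,
            tolerance > 0)
  target <- msp_spec$outcome
  if (!is.null(fixed_csps)) specs <- .set_csps(specs, fixed_csps)
  rng <- sort(initial_range)
  trace <- list()
  eval_msp <- function(csp_val) {
    .impute_and_measure(data, specs,
                        stats::setNames(csp_val, target),
                        list(msp_spec), NULL, NULL, m, cycles, seed)$msp[[1]]
  }
  for (round in seq_len(max_rounds)) {
    test_vals <- seq(rng[1], rng[2], length.out = n_test)
    msp_hat <- vapply(test_vals, eval_msp, numeric(1))
    trace[[round]] <- data.frame(round = round, csp = test_vals,
                                 msp = msp_hat)
    if (round == 1L && (elicited < min(msp_hat) || elicited > max(msp_hat)))
      stop("elicited MSP ", elicited, " lies outside the achieved MSP range [",
           sprintf("%.4g, %.4g", min(msp_hat), max(msp_hat)),
           "] of the initial CSP range; widen the initial range")
    below <- which(msp_hat <= elicited)
    above <- which(msp_hat >= elicited)
    lo_i <- if (length(below)) below[which.max(msp_hat[below])] else which.min(msp_hat)
    hi_i <- if (length(above)) above[which.min(msp_hat[above])] else which.max(msp_hat)
    if (abs(msp_hat[hi_i] - msp_hat[lo_i]) <= tolerance) {
      best <- if (abs(msp_hat[lo_i] - elicited) <= abs(msp_hat[hi_i] - elicited))
        lo_i else hi_i
      return(structure(list(
        calibrated = test_vals[best], achieved_msp = msp_hat[best],
        converged = TRUE, rounds = round, target = target,
        elicited = elicited, tolerance = tolerance,
        trace = do.call(rbind, trace), seed = seed),
        class = "calibration_result"))
    }
    rng <- sort(c(test_vals[lo_i], test_vals[hi_i]))
    if (diff(rng) == 0) rng <- rng + c(-1, 1) * tolerance
  }
  tr <- do.call(rbind, trace)
  best <- which.min(abs(tr$msp - elicited))
  structure(list(calibrated = tr$csp[best], achieved_msp = tr$msp[best],
                 converged = FALSE, rounds = max_rounds, target = target,
                 elicited = elicited, tolerance = tolerance, trace = tr,
                 seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result")
  if (!is.null(x$target)) cat(" (one-at-a-time, target '", x$target, "')", sep = "")
  cat("\n")
  if (!is.null(x$converged))
    cat("  converged:", x$converged, "in", x$rounds, "round(s)\n")
  if (is.numeric(x$calibrated) && length(x$calibrated) == 1L)
    cat(sprintf("  calibrated CSP: %.6g (achieved MSP %.6g, elicited %.6g)\n",
                x$calibrated, x$achieved_msp, x$elicited))
  if (is.data.frame(x$calibrated) && nrow(x$calibrated))
    cat("  qualifying vectors:", nrow(x$calibrated), "\n")
  if (!is.null(x$coverage))
    cat("  elicited-range coverage:",
        paste(sprintf("%s=%s", names(x$coverage), x$coverage), collapse = ", "),
        "\n")
  invisible(x)
}

#' Empirical check of the one-at-a-time assumption
#'
#' From an [calibrate_grid()] result whose grid varies at least two
#' variables, computes for each variable the difference CSP minus
#' achieved MSP at every grid point and measures how much that difference
#' moves across the settings of the *other* CSPs (at each fixed own-CSP
#' value).  If the maximal spread stays below `threshold` (a Monte Carlo
#' noise allowance, not a universal constant), calibrating one variable
#' at a time is empirically justified.
#'
#' @param result a `calibration_result` from [calibrate_grid()].
#' @param threshold pass threshold on the MSP scale (default 0.1).
#' @return List with per-variable `spread`, the `threshold`, and `pass`.
#' @export
check_one_at_a_time <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "calibration_result"))
  tab <- result$grid
  vars <- sub("^csp_", "", grep("^csp_", names(tab), value = TRUE))
  spread <- vapply(stats::setNames(vars, vars), function(v) {
    d <- tab[[paste0("csp_", v)]] - tab[[paste0("msp_", v)]]
    groups <- split(d, tab[[paste0("csp_", v)]])
    if (all(lengths(groups) < 2L))
      stop("grid has a single setting of the other CSPs for '", v,
           "'; the one-at-a-time check needs at least two")
    max(vapply(groups, function(g) diff(range(g)), numeric(1)))
  }, numeric(1))
  list(spread = spread, threshold = threshold,
       pass = all(spread <= threshold))
}

#' Generalised calibration curve
#'
#' Sweeps one variable's CSP over a range of values (same fixed seed at
#' each point, other CSPs fixed at their spec values) and records a
#' user-chosen interpretable summary of the completed data alongside the
#' pooled effect of interest, for plotting effect against summary.  With
#' `summary_fn` computing the MSP-model indicator coefficient this
#' reproduces the [calibrate_grid()] sweep.
#'
#' @param data,specs,analysis,m,cycles,seed as in [calibrate_grid()].
#' @param target variable whose CSP is varied.
#' @param csp_values numeric vector of CSP test values.
#' @param summary_fn function mapping one completed data frame to a
#'   scalar; the reported summary is its average over the m imputations.
#' @return Data frame with columns `csp_<target>`, `summary`, and the
#'   effect columns when `analysis` is given.
#' @export
generalized_curve <- function(data, specs, target, csp_values, summary_fn,
                              analysis = NULL, m = 10, cycles = 10, seed) {
  stopifnot(is.function(summary_fn))
  grid <- stats::setNames(data.frame(csp_values), target)
  .sweep_grid(data, specs, grid, list(), analysis, summary_fn,
              m, cycles, seed)
}
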