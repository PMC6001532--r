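#' Specify a NARFCS imputation model for one incomplete variable
#'
#' The model regresses the target on `vars` (other variables in the data,
#' at their current completed values) and on the missingness-indicator
#' columns in `indicators`; the target's own indicator is never fitted —
#' its coefficient is the conditional sensitivity parameter (CSP) `csp`,
#' added as an offset to the linear predictor of the rows being imputed.
#' With `csp = 0` and `indicators` empty the model reduces to a plain FCS
#' (MICE-style) univariate model.
#'
#' @param target name of the incomplete variable.
#' @param csp the CSP: units of the target for `family = "gaussian"`,
#'   log-odds for `family = "binomial"`. Must be finite.
#' @param family `"gaussian"` or `"binomial"`.
#' @param vars predictor variable names (default: filled in from
#'   [build_predictor_set()] by [make_narfcs_specs()]).
#' @param indicators cross-indicator column names (`M_<other var>`).
#' @return A `narfcs_spec` object.
#' @export
narfcs_spec <- function(target, csp = 0, family = c("gaussian", "binomial"),
                        vars = NULL, indicators = character(0)) {
  family <- match.arg(family)
  if (!is.numeric(csp) || length(csp) != 1L || !is.finite(csp))
    stop("csp for '", target, "' must be a single finite number")
  structure(list(target = target, csp = csp, family = family,
                 vars = vars, indicators = indicators,
                 csp_term = paste0("M_", target)),
            class = "narfcs_spec")
}

#' Build NARFCS model specs for every incomplete variable
#'
#' Predictor sets come from [build_predictor_set()]: all other variables
#' plus every estimable cross-indicator (dropped cross-indicators are
#' reported via a message).  Set `include_indicators = FALSE` for plain
#' FCS models (no missingness indicators anywhere; combined with zero
#' CSPs this is standard MAR imputation).
#'
#' @param data an [incomplete_data()] object.
#' @param csp named numeric vector of CSPs (one per incomplete variable;
#'   unnamed scalar 0 recycles). Names must match incomplete variables.
#' @param family per-variable family, recycled (default gaussian).
#' @param include_indicators include cross-indicators and apply the CSP
#'   machinery (default TRUE).
#' @param cond_tol passed to [build_predictor_set()].
#' @return List of [narfcs_spec()] objects, one per incomplete variable in
#'   the dataset's column order.
#' @export
make_narfcs_specs <- function(data, csp = 0, family = "gaussian",
                              include_indicators = TRUE, cond_tol = 1e8) {
  stopifnot(inherits(data, "incomplete_data"))
  targets <- data$incomplete
  if (length(csp) == 1L && is.null(names(csp)))
    csp <- stats::setNames(rep(csp, length(targets)), targets)
  if (!all(targets %in% names(csp)))
    stop("csp must be named for every incomplete variable: ",
         paste(setdiff(targets, names(csp)), collapse = ", "))
  extra <- setdiff(names(csp), targets)
  if (length(extra))
    stop("CSP specified for complete or unknown variable: ",
         paste(extra, collapse = ", "))
  family <- rep_len(family, length(targets))
  lapply(seq_along(targets), function(k) {
    t <- targets[k]
    ps <- build_predictor_set(data, t, cond_tol = cond_tol)
    if (length(ps$dropped))
      message("NARFCS model for '", t, "': dropped non-estimable indicator(s) ",
              paste(ps$dropped, collapse = ", "))
    narfcs_spec(t, csp = csp[[t]], family = family[k], vars = ps$vars,
                indicators = if (include_indicators) ps$indicators else character(0))
  })
}

# design matrix for one spec at the current completed values
.design <- function(values, indicators, spec) {
  cbind(`(Intercept)` = rep(1, nrow(values)),
        values[, spec$vars, drop = FALSE],
        indicators[, spec$indicators, drop = FALSE])
}

#' Bayesian draw from a normal linear model posterior
#'
#' Proper-imputation parameter draw under the standard noninformative
#' prior: residual variance from its scaled inverse-chi-square posterior,
#' then coefficients from their conditional normal posterior.  Uses the
#' global RNG; the draw order is fixed (one chi-square deviate, then
#' `ncol(design)` standard normals), which downstream seed-replay relies
#' on.
#'
#' @param outcome numeric outcome vector (observed rows).
#' @param design numeric design matrix, same number of rows.
#' @param var_floor lower bound on the drawn residual variance, a
#'   numerical guard for degenerate (near-constant) outcomes.
#' @return List with `coef` (drawn coefficients, named as the design
#'   columns) and `sigma` (drawn residual SD).
#' @export
draw_linear_model <- function(outcome, design, var_floor = 1e-10) {
  n <- nrow(design); p <- ncol(design)
  if (n < p + 2L)
    stop("too few observed rows (", n, ") to fit ", p, " coefficients")
  qrx <- qr(design)
  if (qrx$rank < p) {
    aliased <- colnames(design)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design matrix rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  betahat <- qr.coef(qrx, outcome)
  rss <- sum(qr.resid(qrx, outcome)^2)
  sigma2 <- max(rss / stats::rchisq(1L, n - p), var_floor)
  sigma <- sqrt(sigma2)
  z <- stats::rnorm(p)
  R <- qr.R(qrx)
  beta <- betahat
  beta[qrx$pivot] <- beta[qrx$pivot] + sigma * drop(backsolve(R, z))
  list(coef = beta, sigma = sigma)
}

# approximate Bayesian draw for a logistic model: MLE plus a normal
# perturbation from the asymptotic covariance (the classical "logreg"
# device).  No paper-anchored validation exists for this family.
.draw_logistic_model <- function(outcome, design) {
  n <- nrow(design); p <- ncol(design)
  if (n < p + 2L)
    stop("too few observed rows (", n, ") to fit ", p, " coefficients")
  fit <- suppressWarnings(
    stats::glm.fit(design, outcome, family = stats::binomial()))
  betahat <- fit$coefficients
  if (anyNA(betahat))
    stop("design matrix rank deficient; aliased terms: ",
         paste(names(betahat)[is.na(betahat)], collapse = ", "))
  w <- fit$weights
  V <- chol2inv(chol(crossprod(design * sqrt(w))))
  beta <- betahat + drop(chol(V) %*% stats::rnorm(p))
  list(coef = beta, sigma = NA_real_)
}

#' Impute the missing cells of one variable
#'
#' Fits the estimable portion of the NARFCS model on the rows where the
#' target is observed (i.e. the model given `M_target = 0` and the other
#' indicators), then adds the CSP to the linear predictor of the missing
#' rows only and draws from the shifted predictive distribution: normal
#' for the gaussian family, Bernoulli on the shifted logit for binomial.
#'
#' @param values current completed numeric matrix (all predictors filled).
#' @param indicators the fixed missingness-indicator matrix.
#' @param miss_target logical vector flagging the target's missing rows.
#' @param spec a [narfcs_spec()].
#' @return Numeric vector of imputed values, one per missing row.
#' @export
impute_one_variable <- function(values, indicators, miss_target, spec) {
  X <- .design(values, indicators, spec)
  obs <- !miss_target
  y <- values[obs, spec$target]
  n_mis <- sum(miss_target)
  if (spec$family == "gaussian") {
    par <- draw_linear_model(y, X[obs, , drop = FALSE])
    lp <- drop(X[miss_target, , drop = FALSE] %*% par$coef) + spec$csp
    stats::rnorm(n_mis, lp, par$sigma)
  } else {
    par <- .draw_logistic_model(y, X[obs, , drop = FALSE])
    lp <- drop(X[miss_target, , drop = FALSE] %*% par$coef) + spec$csp
    stats::rbinom(n_mis, 1L, stats::plogis(lp))
  }
}

# deterministic sub-seed derivation: one independent stream per imputation
.derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, k)
}

#' Run NARFCS / FCS chained-equations multiple imputation
#'
#' For each of `m` imputations: every incomplete variable is first filled
#' by sampling with replacement from its observed values, then the
#' variables are visited in spec order for `cycles` cycles, each visit
#' refitting the variable's model on its observed rows (via
#' [impute_one_variable()]) and redrawing its missing cells.  Each
#' imputation runs on its own RNG sub-stream derived from `seed`, so runs
#' are bit-reproducible and the m imputations are independent.
#'
#' @param data an [incomplete_data()] object.
#' @param specs list of [narfcs_spec()] covering every incomplete variable
#'   (e.g. from [make_narfcs_specs()]).
#' @param m number of imputed datasets (default 10).
#' @param cycles chained-equation cycles per imputation (default 10).
#' @param seed integer master seed (required for reproducibility).
#' @return A `narfcs_imp` object: list with `completed` (list of `m`
#'   data frames containing the completed variables and the indicator
#'   columns), `miss` (the original missingness mask, i.e. which cells
#'   were imputed), `m`, `cycles`, `seed`, `specs`.
#' @examples
#' d <- data.frame(y1 = c(rnorm(50), rep(NA, 10)), y2 = rnorm(60))
#' inc <- incomplete_data(d)
#' imp <- narfcs_impute(inc, make_narfcs_specs(inc, csp = c(y1 = -1)),
#'                      m = 2, cycles = 3, seed = 7)
#' @export
narfcs_impute <- function(data, specs, m = 10, cycles = 10, seed) {
  stopifnot(inherits(data, "incomplete_data"), m >= 1L, cycles >= 1L)
  if (inherits(specs, "narfcs_spec")) specs <- list(specs)
  spec_targets <- vapply(specs, `[[`, character(1), "target")
  if (!setequal(spec_targets, data$incomplete))
    stop("specs must cover exactly the incomplete variables; missing: ",
         paste(setdiff(data$incomplete, spec_targets), collapse = ", "),
         if (length(setdiff(spec_targets, data$incomplete)))
           paste0("; extraneous: ",
                  paste(setdiff(spec_targets, data$incomplete), collapse = ", ")))
  if (missing(seed)) stop("a master seed is required")
  seeds <- .derive_seeds(seed, m)
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(seeds[i])
    V <- data$values
    for (spec in specs) {
      mis <- data$miss[, spec$target]
      obs_vals <- V[!mis, spec$target]
      V[mis, spec$target] <- sample(obs_vals, sum(mis), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (spec in specs) {
        mis <- data$miss[, spec$target]
        V[mis, spec$target] <- tryCatch(
          impute_one_variable(V, data$indicators, mis, spec),
          error = function(e) stop("imputation ", i, ", cycle ", cy,
                                   ", variable '", spec$target, "': ",
                                   conditionMessage(e), call. = FALSE))
      }
    }
    completed[[i]] <- data.frame(V, data$indicators, check.names = FALSE)
  }
  structure(list(completed = completed, miss = data$miss, m = m,
                 cycles = cycles, seed = seed, specs = specs,
                 var_names = data$var_names, incomplete = data$incomplete),
            class = "narfcs_imp")
}

#' @export
print.narfcs_imp <- function(x, ...) {
  cat("NARFCS imputation: m =", x$m, ", cycles =", x$cycles,
      ", seed =", x$seed, "\n")
  cat("  incomplete variables:", paste(x$incomplete, collapse = ", "), "\n")
  csps <- vapply(x$specs, `[[`, numeric(1), "csp")
  cat("  CSPs:", paste(sprintf("%s=%.4g",
      vapply(x$specs, `[[`, character(1), "target"), csps), collapse = ", "),
      "\n")
  invisible(x)
}
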