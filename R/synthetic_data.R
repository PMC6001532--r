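#' Simulate one dataset from the Gaussian pattern-mixture process
#'
#' Draws independent Bernoulli missingness indicators (M1, M2), then
#' (Y1, Y2) bivariate normal with the pattern-specific means and the
#' common covariance, then masks Y_j wherever M_j = 1.  Missingness is
#' independent of Y given the pattern by construction.  The pre-masking
#' truth is kept as an attribute for parameter-recovery checks only; the
#' imputation engine never sees it.
#'
#' @param params a [gaussian_pm_params()] object.
#' @param n number of subjects (>= 1).
#' @param seed integer seed.
#' @return An [incomplete_data()] object with columns `Y1`, `Y2` and
#'   attributes `truth` (complete n x 2 matrix before masking) and
#'   `params`.
#' @export
simulate_pm <- function(params, n, seed) {
  stopifnot(inherits(params, "gaussian_pm_params"), n >= 1L)
  p <- params
  set.seed(seed)
  m1 <- stats::rbinom(n, 1L, p$pi1)
  m2 <- stats::rbinom(n, 1L, p$pi2)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  y1 <- p$mu10 + p$mu11 * m1 + p$mu12 * m2 + p$sigma1 * z1
  y2 <- p$mu20 + p$mu21 * m1 + p$mu22 * m2 +
    p$sigma2 * (p$rho * z1 + sqrt(1 - p$rho^2) * z2)
  truth <- cbind(Y1 = y1, Y2 = y2)
  y1[m1 == 1L] <- NA_real_
  y2[m2 == 1L] <- NA_real_
  out <- incomplete_data(data.frame(Y1 = y1, Y2 = y2))
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}

#' Simulate independent replicate datasets
#'
#' Replicates [simulate_pm()] with one RNG sub-stream per replicate
#' derived from the master seed, so any replicate can be regenerated in
#' isolation.
#'
#' @param params a [gaussian_pm_params()] object.
#' @param n subjects per replicate.
#' @param n_datasets number of replicates.
#' @param seed master seed.
#' @return List of [incomplete_data()] objects.
#' @export
simulate_study <- function(params, n, n_datasets, seed) {
  seeds <- .derive_seeds(seed, n_datasets)
  lapply(seq_len(n_datasets), function(r) simulate_pm(params, n, seeds[r]))
}
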