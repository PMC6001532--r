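#' Parameters of the bivariate-Gaussian pattern-mixture model
#'
#' The model for two continuous incomplete variables (Y1, Y2) with
#' independent Bernoulli missingness indicators (M1, M2):
#' given the pattern, (Y1, Y2) is bivariate normal with means
#' `mu10 + mu11*M1 + mu12*M2` and `mu20 + mu21*M1 + mu22*M2` and a
#' pattern-invariant covariance built from `sigma1`, `sigma2`, `rho`.
#' `mu11` and `mu22` — the shifts of each variable associated with its own
#' missingness, marginal on the other Y — are the model's marginal
#' sensitivity parameters (MSPs).
#'
#' @param mu10,mu11,mu12 mean structure of Y1 (baseline, own-indicator
#'   shift = MSP, other-indicator shift).
#' @param mu20,mu21,mu22 mean structure of Y2 (`mu22` is its MSP).
#' @param sigma1,sigma2 positive marginal SDs.
#' @param rho correlation, strictly inside (-1, 1) for the conditionals to
#'   exist (|rho| = 1 is accepted here but rejected by
#'   [full_conditionals()]).
#' @param pi1,pi2 missingness probabilities in `[0, 1]`.
#' @return A `gaussian_pm_params` object (named list).
#' @export
gaussian_pm_params <- function(mu10, mu11, mu12, mu20, mu21, mu22,
                               sigma1, sigma2, rho, pi1, pi2) {
  stopifnot(sigma1 > 0, sigma2 > 0, abs(rho) <= 1,
            pi1 >= 0, pi1 <= 1, pi2 >= 0, pi2 <= 1)
  structure(list(mu10 = mu10, mu11 = mu11, mu12 = mu12,
                 mu20 = mu20, mu21 = mu21, mu22 = mu22,
                 sigma1 = sigma1, sigma2 = sigma2, rho = rho,
                 pi1 = pi1, pi2 = pi2),
            class = "gaussian_pm_params")
}

#' Full-conditional (NARFCS-equivalent) models of the pattern mixture
#'
#' The imputation models equivalent to the bivariate pattern-mixture
#' model are its full conditionals.  For Y1 given (Y2, M1, M2):
#' intercept `mu10 - rho*(s1/s2)*mu20`, slope on Y2 `rho*(s1/s2)`,
#' own-indicator coefficient (the CSP) `mu11 - rho*(s1/s2)*mu21`,
#' other-indicator coefficient `mu12 - rho*(s1/s2)*mu22`, residual SD
#' `s1*sqrt(1-rho^2)`; symmetrically for Y2.  Each coefficient is coded as
#' its own expression so it is separately testable.
#'
#' @param params a [gaussian_pm_params()] object.
#' @return List with elements `Y1` and `Y2`, each a `conditional_model`:
#'   `intercept`, `coef_other_y`, `csp` (own-indicator coefficient),
#'   `coef_other_indicator`, `residual_sd`; plus `msp` (the marginal
#'   sensitivity parameter, for reference).
#' @examples
#' p <- gaussian_pm_params(10, -2, 1, 20, 1, -3, 2, 4, 0.6, 0.3, 0.25)
#' full_conditionals(p)$Y1$csp   # -2.3
#' @export
full_conditionals <- function(params) {
  stopifnot(inherits(params, "gaussian_pm_params"))
  p <- params
  if (abs(p$rho) >= 1) stop("|rho| = 1: conditional distributions are degenerate")
  r12 <- p$rho * p$sigma1 / p$sigma2
  r21 <- p$rho * p$sigma2 / p$sigma1
  y1 <- structure(list(
    intercept = p$mu10 - r12 * p$mu20,
    coef_other_y = r12,
    csp = p$mu11 - r12 * p$mu21,
    coef_other_indicator = p$mu12 - r12 * p$mu22,
    residual_sd = p$sigma1 * sqrt(1 - p$rho^2),
    msp = p$mu11), class = "conditional_model")
  y2 <- structure(list(
    intercept = p$mu20 - r21 * p$mu10,
    coef_other_y = r21,
    csp = p$mu22 - r21 * p$mu12,
    coef_other_indicator = p$mu21 - r21 * p$mu11,
    residual_sd = p$sigma2 * sqrt(1 - p$rho^2),
    msp = p$mu22), class = "conditional_model")
  list(Y1 = y1, Y2 = y2)
}

#' Marginal means implied by the pattern-mixture parameters
#'
#' Averaging the pattern-specific means over the independent missingness
#' patterns: `E(Y1) = mu10 + mu11*pi1 + mu12*pi2` and
#' `E(Y2) = mu20 + mu21*pi1 + mu22*pi2`.
#'
#' @param params a [gaussian_pm_params()] object.
#' @return Named numeric vector `c(Y1 = ..., Y2 = ...)`.
#' @export
marginal_means <- function(params) {
  stopifnot(inherits(params, "gaussian_pm_params"))
  p <- params
  c(Y1 = p$mu10 + p$mu11 * p$pi1 + p$mu12 * p$pi2,
    Y2 = p$mu20 + p$mu21 * p$pi1 + p$mu22 * p$pi2)
}

#' CSP under the blood-pressure-style dampening restriction
#'
#' In the special case where only Y1's model carries indicator terms
#' (`mu12 = mu22 = 0` and the other-indicator coefficient in the Y2
#' conditional is zero, i.e. `mu21 = rho*(sigma2/sigma1)*mu11`), the CSP
#' for Y1 collapses to `(1 - rho^2) * mu11`: the conditional and marginal
#' shifts differ exactly by the factor (1 - rho^2), the "dampening" once
#' attributed to the chained-equations algorithm inflating the offset.
#'
#' @param mu11 the MSP for Y1.
#' @param rho the correlation.
#' @return The CSP `(1 - rho^2) * mu11`.
#' @export
dampening_csp <- function(mu11, rho) {
  (1 - rho^2) * mu11
}
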