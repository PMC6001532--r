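---
title: "MNAR imputation with NARFCS and calibrated sensitivity parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MNAR imputation with NARFCS and calibrated sensitivity parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narfcs)
```

## The problem

Multiple imputation by chained equations (FCS/MICE) imputes each
incomplete variable $Y_j$ from a univariate conditional model
$P(Y_j \mid X, Y_{-j})$, cycling through the variables until the
imputations stabilise, and pools the per-imputation analyses by Rubin's
rules. This is valid when data are missing at random (MAR). When
missingness plausibly depends on the unobserved values themselves
(missing not at random, MNAR), the analyst needs a sensitivity analysis
that imputes under explicit departures from MAR.

The not-at-random FCS procedure (NARFCS) extends each univariate model
with the missingness indicators $M = (M_1, \dots, M_p)$, $M_j = 1$ when
$Y_j$ is missing:

$$
E(Y_j \mid X, Y_{-j}, M) \;=\;
Z_j^\top\beta_j \;+\; \delta_j M_j ,
$$

where $Z_j$ collects the other variables, the complete covariates and
the *other* indicators $M_{-j}$. The coefficient $\delta_j$ on the
variable's own indicator cannot be estimated from the data — on the rows
used to fit the model $M_j$ is identically zero — so it is supplied by
the user: in each cycle the estimable part of the model is fitted on the
rows with $Y_j$ observed, $\delta_j$ is added to the linear predictor of
the missing rows, and imputations are drawn from the shifted posterior
predictive distribution. Setting every $\delta_j = 0$ does **not**
reduce NARFCS to FCS, because the $M_{-j}$ terms remain; dropping those
terms as well recovers plain FCS exactly (this reduction is verified
bit-for-bit in the test suite against an independent transcription of
the chained-equations contract).

## Conditional versus marginal sensitivity parameters

$\delta_j$ is a *conditional* sensitivity parameter (CSP): the mean
difference between a non-respondent and a respondent **matched on all
other variables and their missingness indicators**. Experts cannot
realistically quantify such a conditional contrast. What they can
quantify is a *marginal* sensitivity parameter (MSP): the coefficient
$\mu_j$ of $M_j$ in a simple pattern-mixture regression such as

$$ E(Y_j \mid M_j) = \mu_{j,0} + \mu_j M_j , $$

i.e. "missing individuals score $\mu_j$ lower than observed ones, on
average". The two parameters differ algebraically whenever the variables
are correlated, and inserting an elicited MSP where the engine expects a
CSP produces imputations inconsistent with the elicited belief. The
package's purpose is to make that distinction operational: the engine
consumes CSPs, the elicitation happens on MSPs, and the calibration
machinery maps one to the other.

### The bivariate Gaussian pattern mixture

For two jointly normal incomplete variables the mapping is available in
closed form and anchors all of the package's oracle tests. The model is

$$
\begin{pmatrix} Y_1 \\ Y_2 \end{pmatrix} \Bigm| M \sim
N\!\left(
\begin{pmatrix}
\mu_{10} + \mu_{11} M_1 + \mu_{12} M_2 \\
\mu_{20} + \mu_{21} M_1 + \mu_{22} M_2
\end{pmatrix},
\begin{pmatrix}
\sigma_1^2 & \rho\sigma_1\sigma_2 \\
\rho\sigma_1\sigma_2 & \sigma_2^2
\end{pmatrix}
\right),
$$

with $M_1, M_2$ independent Bernoulli$(\pi_1, \pi_2)$. Here $\mu_{11}$
and $\mu_{22}$ are the MSPs. The NARFCS models equivalent to this joint
model are its full conditionals; `full_conditionals()` codes each
coefficient symbol-for-symbol, in particular the CSPs

$$
\delta_1 = \mu_{11} - \rho\frac{\sigma_1}{\sigma_2}\,\mu_{21},
\qquad
\delta_2 = \mu_{22} - \rho\frac{\sigma_2}{\sigma_1}\,\mu_{12},
$$

with residual SDs $\sigma_j\sqrt{1-\rho^2}$, and `marginal_means()`
returns $E(Y_j)$ by averaging the pattern means over the patterns. In
the special case where only $Y_1$'s model carries indicator terms, the
CSP collapses to $(1-\rho^2)\mu_{11}$ (`dampening_csp()`): the
historically puzzling "inflation" of delta-adjusted imputations relative
to the specified offset is exactly the conditional-versus-marginal gap,
not an artefact of the cycling algorithm.

```{r analytic}
p <- gaussian_pm_params(mu10 = 10, mu11 = -2, mu12 = 1,
                        mu20 = 20, mu21 = 1, mu22 = -3,
                        sigma1 = 2, sigma2 = 4, rho = 0.6,
                        pi1 = 0.3, pi2 = 0.25)
fc <- full_conditionals(p)
c(csp_Y1 = fc$Y1$csp, csp_Y2 = fc$Y2$csp)
marginal_means(p)
```

This parameter set — moderate correlation, unequal scales, 30% and 25%
missingness — is the package's reference study condition: the MSPs are
$(-2, -3)$ while the CSPs are $(-2.3, -4.2)$, a gap large enough for
misuse to be visibly harmful.

## Calibration algorithms

All three algorithms share one primitive: impute the data with a
candidate CSP vector **under a fixed RNG seed**, fit the MSP models to
the completed data by pooled regression, and read off the achieved MSPs.
The fixed seed makes the achieved MSP a deterministic function of the
CSP vector, so the search is a well-posed root-finding problem.

* `calibrate_grid()` (elicited *ranges*): sweeps the Cartesian grid of
  CSP test values, records achieved MSPs and the pooled effect of
  interest at each point, and checks that the achieved MSP ranges cover
  the elicited ranges, recommending wider or recentred test ranges when
  they do not. Sensitivity analysis is then a tabulation of effect
  against achieved MSP. At most about ten test values per variable are
  recommended — the grid is a full product and each point is a complete
  multiple imputation.
* `calibrate_joint()` (elicited *points*, all CSPs at once): repeats the
  grid sweep coarse-to-fine, shrinking each variable's range to the test
  values bracketing its elicited MSP, until a vector meets all
  tolerances. Several vectors can qualify; all are returned and the one
  minimising the maximum tolerance-standardised deviation is designated
  primary (an explicit tie-break, since multiplicity is real).
* `calibrate_one_at_a_time()` (elicited points, one variable at a time):
  a bracketing line search per variable with the other CSPs held fixed
  (by default at their elicited MSP values, a sensible centring). It
  stops when the two achieved MSPs bracketing the elicited value agree
  to within the tolerance and returns the closer test value. This is
  the efficient option, but it presumes the *one-at-a-time assumption*:
  the CSP–MSP relationship of one variable does not depend on the other
  variables' CSPs. That holds for Gaussian data with linear models —
  the CSP–MSP map is affine with coefficients depending only on
  $(\rho, \sigma_1, \sigma_2)$ — and is doubtful otherwise;
  `check_one_at_a_time()` verifies it empirically from a grid sweep by
  measuring how much CSP − achieved-MSP moves across the other CSPs'
  settings.

`tipping_point()` reuses the grid sweep to report the p-value surface of
the substantive effect and the first CSP (per axis) at which the
significance conclusion flips, mapped to its achieved MSP so the
plausibility of the tipping departure can be judged on the elicitable
scale. `generalized_curve()` replaces the MSP fit with any user summary
of the completed data, tracing the pooled effect against an
interpretable statistic.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 10 | imputed datasets per run |
| `cycles` | 10 | chained-equation cycles per imputation |
| `tolerance` | 0.001 | convergence tolerance on the MSP scale (units of the outcome) |
| `n_test` | 10 | test values per variable and refinement round |
| `max_rounds` | 10 | refinement-round cap; unconverged results are returned flagged |
| `cond_tol` | 1e8 | condition-number threshold for dropping a cross-indicator |
| `conf_level` | 0.95 | nominal level for pooled intervals |

The `m = 10`/`cycles = 10` defaults are the conventional workhorse
settings for chained-equations sensitivity analysis; tighter calibration
tolerances mainly demand more refinement rounds, not larger `m`, because
the fixed seed removes between-evaluation noise.

## Numerical and design choices

* **Proper imputation.** Gaussian models draw the residual variance from
  its scaled inverse-$\chi^2$ posterior and the coefficients from their
  conditional normal posterior (noninformative prior) before every
  predictive draw — the classical "norm" device that Rubin's rules
  require. A variance floor of $10^{-10}$ guards degenerate
  (near-constant) outcomes; it is numerical safety, not statistics. The
  binomial family uses the asymptotic-normal perturbation of the
  logistic MLE and applies the CSP on the log-odds scale; it is provided
  as an engine extension and has no closed-form oracle here.
* **Seed policy.** A master seed spawns one sub-stream per imputation
  (and per replicate in the simulation harness), so runs are
  bit-reproducible, individual imputations can be regenerated in
  isolation, and identical seeds give identical output — the property
  the fixed-seed calibration sweeps and the replay log rely on.
* **Initial fill and visit order.** Each incomplete variable starts from
  a with-replacement sample of its own observed values; variables are
  visited in spec order each cycle. Both are documented contract, so a
  run is reproducible from the log alone.
* **Estimability of cross-indicators.** A cross-indicator enters a
  model only if, on the rows where the target is observed, it is
  non-constant and does not push the indicator design's condition number
  beyond `cond_tol` (monotone dropout is the canonical failure).
  Removals are reported, never fatal; the variable's own indicator is
  always retained as the CSP term. The threshold rule is this package's
  choice of how to operationalise "include every estimable indicator".
* **Degenerate brackets.** If a refinement round collapses to a
  zero-width bracket, the range is re-inflated by one grid step (joint
  search) or by the tolerance (line search) rather than terminating on a
  spuriously exact match.

## The synthetic-data generator

`simulate_pm()` draws the indicators, then the bivariate normal outcomes
with pattern-specific means, then masks — so missingness is independent
of the outcomes given the pattern by construction, and the pre-masking
truth is retained (as an attribute, invisible to the engine) for
parameter-recovery tests. The generator's default use throughout the
tests is the reference parameter set above with $n = 1000$ per
replicate.

What it deliberately does **not** emulate: covariate-dependent or
longitudinal (monotone-dropout) missingness mechanisms, non-Gaussian
outcomes, and measurement error. Passing tests therefore demonstrate
correctness of the machinery under the Gaussian pattern-mixture ideal —
where every quantity has a closed form to test against — not robustness
of NARFCS on arbitrary real data.

## The simulation harness

`run_simulation_study()` scores three strategies on replicated data from
the generator, pooling intercept-only fits of each outcome and comparing
them with the analytic marginal means: imputing with the exact CSPs (the
unattainable benchmark), inserting the MSPs as if they were CSPs (the
misuse), and imputing with CSPs calibrated by the one-at-a-time search.
Reported metrics are bias, empirical SE, and 95% coverage, each with its
Monte Carlo error (bias MCE $= \widehat{SE}/\sqrt{R}$, empirical-SE MCE
$= \widehat{SE}/\sqrt{2(R-1)}$, coverage MCE
$= 100\sqrt{\hat p(1-\hat p)/R}$; the "max" row uses worst-case
$p = 0.5$). The expected picture is unbiasedness and near-nominal
coverage for the true and calibrated arms, and upward bias with
collapsing coverage for the inserted-MSP arm, worse for the variable
with the larger CSP–MSP gap.

By default the calibrated arm calibrates **once**, on a large auxiliary
dataset ($n = 10^5$) drawn from the same process, and reuses the CSPs
across replicates; per-replicate recalibration is available behind
`calibrate_per_replicate = TRUE` at roughly the cost of one extra
calibration per replicate. Problem sizes used by the shipped checks: the
full-scale study in `scripts/acceptance.R` runs 1000 replicates of
$n = 1000$ with the $n = 10^5$ calibration dataset; the test suite runs
a 200-replicate scaled mode with a $n = 2\times10^4$ calibration dataset
(sufficient for the qualitative arm ordering) plus a single $n = 10^5$
one-at-a-time calibration checked against the closed-form CSPs.

## Known limitations

* Only continuous and binary 0/1 variables are supported; no factors,
  ordinal scales, predictive mean matching, or passive imputation.
* The logistic family is untested against any analytic truth, and the
  one-at-a-time assumption is expected to fail for it; use the joint
  search and the empirical check there.
* The closed-form CSP↔MSP conversion exists only for the bivariate
  Gaussian pattern mixture; for everything else calibration is purely
  computational.
* Monotone/longitudinal missingness is handled only by dropping
  non-estimable indicators, not by a dedicated longitudinal strategy.
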