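---
title: "Weighted survival regression with external prediction weights: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted survival regression with external prediction weights: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survweight)
```

## The model and its estimand

`survweight` fits survival regression models to right-censored data
$(X_i, \delta_i, Z_i)$, $X_i = \min(T_i, C_i)$, $\delta_i = I(T_i \le C_i)$,
in which every subject carries a weight $\hat w_i$ derived from an external
risk prediction model. Estimation solves weighted estimating equations built
from the counting process $N_i(t) = I(X_i \le t, \delta_i = 1)$ and at-risk
process $Y_i(t) = I(X_i \ge t)$:

* **Proportional hazards.** $\hat\beta$ solves
  $U_c(\beta) = \sum_i \hat w_i \delta_i \{Z_i - S^{(1)}(\beta, X_i)/S^{(0)}(\beta, X_i)\} = 0$
  with $S^{(k)}(\beta, t) = \sum_j \hat w_j Y_j(t) Z_j^{(k)} e^{\beta'Z_j}$.
* **Additive hazards (Lin–Ying).** $\hat\alpha$ is the closed-form solution of
  $U_1(\alpha) = \sum_i \hat w_i \int_0^\tau (Z_i - \bar Z_w(t))\{dN_i(t) - Y_i(t)\alpha'Z_i\,dt\} = 0$.

Two consequences drive the whole design. First, with informative weights the
fitted model is a *working* model even when the unweighted model would be
correct, so the estimand is the **least-false parameter** $\beta^*$ (or
$\alpha^*$): the root of the population estimating equation under the true
law. Coefficients are measures of association, not causal hazard ratios or
risk differences. Second, model-based variances are generally wrong; the
package's default inference is the sandwich covariance
($A^{-1}BA^{-1}/n$, resp. $D^{-1}ED^{-1}/n$, with meat matrices formed from
per-subject score residuals / martingale-residual integrals) and, as the
primary tool, perturbation resampling.

### Weight placement

The estimating-equation formulation leaves one genuine ambiguity: whether
the weights enter only through each subject's own $dM_i$ contribution
(risk-set sums unweighted) or also through the risk-set sums. Standard
software with case weights does the latter, and that is what fitting "a
weighted Cox model" means operationally, so the **case-weight convention is
the default** (`weight_placement = "both"`); the alternative reading is
available as `weight_placement = "events-only"`. The two define different
estimators with genuinely different least-false targets; the package treats
the default as primary and the flag as a sensitivity analysis.

### Weight recipes and direction

`weights_from_survival_prob()` uses an external model's predicted survival
probability at a horizon directly as the weight — larger weights for
*lower*-risk subjects. `weights_from_cumulative_hazard()` maps a predicted
cumulative hazard $H$ to $1 - e^{-H}$, i.e. onto the event-probability scale
in $[0, 1)$, so hazard-based (e.g. random-forest) and survival-based weights
are commensurable; this transform is a package choice — raw hazards can be
passed through `as_weights()` if preferred. Both constructors take
`complement = TRUE` to flip direction (up-weighting predicted-high-risk
subjects), since which direction is scientifically right depends on the
analysis goal: emphasising high-risk subjects sharpens association signals
in that stratum, while weighting by agreement with the external model
generally inflates standard errors when the model and the data disagree.
Weights are scalar per subject (constant in $t$); time-varying weight
functions are a declared non-goal. Subjects with weight exactly zero are
retained structurally, contribute to nothing, and trigger a warning.
`normalize_weights()` rescales to mean one; both estimating equations are
homogeneous of degree one in the weights, so this (or any positive
rescaling) never changes a point estimate — a property the tests check to
1e-8.

## Numerical choices

* **PH solver.** Newton–Raphson on the weighted log partial likelihood with
  up to 20 step-halvings per iteration (the likelihood never decreases
  between accepted iterates), convergence at
  $\lVert U_c(\hat\beta)\rVert_\infty \le$ `tol` (default 1e-9, on the total
  score), at most 100 iterations, and divergence declared when
  $\lVert\hat\beta\rVert_\infty > 50$ (monotone likelihood / separation is
  reported as a typed non-convergence error, singular information as a
  singular-matrix error). $e^{\beta'Z}$ is centred by
  $\max_i \beta'Z_i$ inside every risk-set computation to prevent overflow.
* **Ties.** Efron's correction is the default (matching the default of
  standard Cox software); Breslow is available, and is what makes
  integer-weight replication exactly equivalent to row duplication — a
  property used as an exact oracle in the tests.
* **Additive model.** All $t$-integrals are computed exactly as sums over
  the inter-exit-time step structure (the integrands are piecewise constant
  between observed times); there is no quadrature error. $\tau$ defaults to
  the largest observed time and is configurable to guard against sparse
  late-follow-up instability.
* **Perturbation.** Multipliers are i.i.d. Exp(1) — unit mean *and* unit
  variance, as the multiplier theory requires. The uncentred scheme
  ($G_i = V_i \hat w_i$) is implemented: it is the standard multiplier
  bootstrap and what per-subject-weight software produces. Perturbed Cox
  refits warm-start at $\hat\beta$. Failed refits are dropped and counted,
  with an error above a 10% failure rate, at which point percentile
  intervals are no longer trustworthy. Percentile CIs use the
  linear-interpolation quantile definition (`type = 7`), fixed so results
  are bit-reproducible under a seed. `B = 1000` is the default, consistent
  with standard bootstrap practice for percentile intervals.
* **Degenerate inputs.** Validation is report-style (`validate_dataset()`
  returns a tibble of violations) and fitting functions raise typed
  conditions: no events, negative weights or times, non-finite covariates,
  collinear covariates (singular information / dispersion), all-zero
  weights. At tied times, events and censorings alike remain in the risk
  set at $t$ (the standard counting-process convention).

## The synthetic-data module

`dgp_spec()` + `simulate_survival()` generate cohorts by inverse-transform
sampling from fully specified conditional hazards: PH or additive, constant
or Weibull baseline, independent exponential / uniform censoring, and
covariates with *compact support* (Bernoulli, uniform, truncated normal) so
the boundedness assumption of the asymptotic theory holds by construction.
Additive specs that would permit a negative hazard anywhere on the covariate
support are rejected at construction rather than clipped — clipping would
silently change the data-generating law and corrupt the oracle below.
`calibrate_censoring()` solves for the censoring parameter achieving a
target censoring fraction by Monte Carlo root finding.

`external_predictions()` emulates the external-information setting: an
independent external cohort is simulated from the same process, a prediction
model (PH or additive, optionally restricted to a covariate subset — i.e. a
misspecified external model) is built on it, and each analysis subject
receives predictions on both scales, always satisfying $S = e^{-H}$.
`builder = "oracle_true"` bypasses external-fit noise and uses the true
model's predictions, which is what the consistency tests need.

`least_false_oracle()` approximates $\beta^*$/$\alpha^*$ by solving the
weighted estimating equation on a single cohort of `n_oracle = 200000`
subjects with oracle-true weights, rather than by numerical integration of
the population equation: the Monte Carlo route is model-agnostic and its
error is directly quantifiable. The MC standard error comes from refitting
on 20 disjoint blocks of the same cohort ($\mathrm{sd}/\sqrt{20}$), which
prices the oracle's own noise into every "within $k$ combined SEs"
comparison.

What the generator does *not* emulate: dependent censoring, time-varying
covariates or weights, model-form families beyond PH/additive, and the
covariate structure of any particular real cohort. Passing tests therefore
demonstrate the estimation and inference machinery under clean conditions —
they do not certify behaviour under, say, informative censoring, which the
theory itself excludes.

## Reference study conditions

The package's own validation runs (tests and `scripts/acceptance.R`) use two
fixed data-generating processes chosen to be plain but realistic for a
methods check: PH truth with $\lambda_0 = 1$, $\beta = 0.7$,
$Z \sim \mathrm{Bernoulli}(0.5)$; additive truth with $\lambda_0 = 1$,
$\alpha = 0.5$, same covariate; exponential censoring at rate 0.25
(roughly 20% censored); prediction horizon 1 (about the median event time,
where survival predictions are most informative). Problem sizes: $n = 500$
analysis cohorts for calibration and coverage (200 outer replicates,
$B = 1000$), $n = 1000$ with 1000 replicates for sandwich-vs-empirical-SD
checks, $n \in \{250, 1000, 4000, 20000\}$ for the consistency ladder
against the $n = 200000$ oracle. Misspecification is exercised by crossing
the two laws (additive truth fitted with the PH model and vice versa).

## Known limitations

* Scalar (time-constant) weights only; no left truncation, time-dependent
  covariates, stratification, competing risks, or penalised estimation.
* The additive model is the semiparametric constant-coefficient Lin–Ying
  version, not Aalen's time-varying-coefficient model.
* For `weight_placement = "events-only"` the additive-model sandwich reuses
  the case-weight influence decomposition with the unweighted at-risk mean;
  its per-subject contributions then no longer sum exactly to zero, so the
  sandwich there is approximate (the default placement is exact).
* External predictions are consumed as columns; the package never trains a
  random survival forest or any other external model, and calibration of
  the external model is the user's responsibility.
* The weighted analysis can be extremely sensitive to near-zero weights
  (subjects the external model deems certain to have the event): in the
  Mayo PBC example the weighted treatment estimate varies substantially
  with how such predictions are handled. Inspect the weight distribution
  (`run_fit()` logs min/median/max) before interpreting weighted estimates.
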