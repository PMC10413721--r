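---
title: "Longitudinal matching for time-dependent treatments: models, design choices, and simulation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal matching for time-dependent treatments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmatch)
```

## The problem

Many treatments in observational health data are *static but accessible at
multiple time points*: a patient either never starts treatment or starts it
once, at some interval during follow-up. Covariates that evolve during the
waiting period — disease severity, lab values, intercurrent events — affect
both *when* treatment starts and the outcome, producing time-dependent
confounding. Matching ever-treated to never-treated patients on baseline
covariates alone ignores this drift and produces biased contrasts (including
immortal-time bias). `longmatch` implements and compares three estimators in
a Monte Carlo framework built for exactly this setting:

1. **Baseline propensity-score matching** — 1:1 nearest-neighbour matching of
   ever-treated to never-treated subjects on a logistic propensity score
   estimated from first-interval covariate values, treating assignment as if
   it happened at baseline. This is the (deliberately naive) reference
   method.
2. **Sequential risk-set matching on a time-dependent propensity score** —
   at each interval `t` with new treatment starts, treated subjects are
   matched to not-yet-treated subjects in the risk set `R_t` on the linear
   predictor of a Cox proportional-hazards model for time to treatment with
   time-dependent covariates. Because the baseline hazard cancels from score
   differences, the linear predictor is the operative "proxied" propensity
   score.
3. **Longitudinal genetic matching** — within each risk set, subjects are
   matched on a weighted generalized Mahalanobis distance
   `d(i,j)^2 = (x_i - x_j)' (S^{-1/2})' W (S^{-1/2}) (x_i - x_j)`,
   with `S^{-1/2}` the inverse lower Cholesky factor of the within-risk-set
   covariance and `W` a non-negative diagonal weight matrix chosen by an
   evolutionary search that maximizes covariate balance. The search uses
   lexical optimization over the sorted vector of balance p-values
   (bootstrapped Kolmogorov–Smirnov tests for continuous variables, weighted
   paired t-tests for binary ones): improve the worst-balanced variable
   first, then the next-worst, and so on.

All matching is 1:1 with replacement; exact ties (distances equal within
`1e-12`) are all kept with weight `1/k`, and those weights propagate as
frequency weights into every downstream mean, variance, ECDF and test.

## The data-generating process

Each simulated panel has `n` subjects (default 1,000) observed over `T = 6`
bi-monthly intervals, with twelve covariates: six binary Bernoulli(0.5) and
six continuous, of which three binary and three continuous are
time-dependent. In the base case, x1–x5 are Bernoulli(0.5) (x4, x5, x11
time-dependent "on-off"), x6–x10 are N(0,1) (x9, x10, x12 time-dependent
with AR(1) dynamics).

Draws come from a latent Gaussian copula. Each covariate has a latent
standard-normal path: constant over time (time-invariant), independently
redrawn each interval (binary on-offs), or AR(1)/MA(1) with innovations
scaled to keep a stationary unit variance. Exchangeable cross-covariate
correlation `rho` is induced by a subject-level shared factor:
`Z_k = sqrt(rho) U + sqrt(1 - rho) V_k`. Binary covariates threshold the
latent normal at the appropriate quantile; Poisson and gamma covariates (one
scenario) use the inverse-CDF transform of the latent normal, with the
autocorrelation placed on the latent scale so the marginal is preserved at
every interval. Two consequences are worth noting: for thresholded binaries
the realized Pearson correlation is attenuated relative to the latent `rho`
(tetrachoric-style), and with `rho > 0` the shared subject-level factor adds
a persistent component to time-dependent covariates. Both are inherent to
imposing one exchangeable correlation across mixed marginals.

Treatment is assigned sequentially: at each interval, every not-yet-treated
subject starts treatment with probability
`plogis(alpha_0 + linear predictor)` evaluated on current covariate values;
treated subjects leave the risk pool (at most one treatment per subject, no
anticipation of future covariates). The base-case assignment model is
non-linear and non-additive (terms `x4*x5`, `x7^2`, `x9^2`, `x6*x9^2`);
effect sizes use the low/medium/high coefficients `log(1.25)`, `log(1.5)`,
`log(1.75)`. Scenario A replaces this with a linear-additive model — the
only scenario in which the fitted propensity models have the correct
functional form. The intercept `alpha_0` is not a free parameter: it is
calibrated by bisection (ever-treated fraction is monotone in the intercept,
and pilot draws are reused across evaluations as common random numbers) so
that one third of subjects are ever treated. We calibrate each scenario to
the same 1/3 rate so that risk-set sizes are comparable across scenarios.

The outcome is continuous:
`y_it = theta * z_it + f(x_it) + e_it`, with true effect `theta = 1`,
`z_it` the treated-at-or-before-t indicator, `f` a linear combination of
x1–x3, x5, x6–x8, x10, x11, x12 with the same low/medium/high coefficients,
and `e_it ~ N(0, sigma^2)`. The outcome model as printed in the source
material carries no error term, but replicate-to-replicate variance of the
effect estimator requires one; we default to `sigma = 1` and expose it
(including `sigma = 0`) as configuration. Covariates x11 and x12 appear only
in the outcome model; their marginals are not pinned down by the scenario
table, so we complete the 6/6 binary–continuous and 3+3 time-dependent split
with x11 ~ Bernoulli(0.5) on-off and x12 ~ N(0,1) AR(1), both excluded from
every propensity model and from matching. Binary "on-off" dynamics are
independent redraws per interval — the simplest reading of an on-off
process; AR(1)/MA(1) parameters default to `phi = 0.5`, `theta = 0.5`
(unstated in the source material; moderate persistence, marginals
preserved), all configurable.

Seven registered scenarios (`scenario_registry()`): base; A (correct
functional form); B, C (latent exchangeable `rho` 0.2, 0.7); D (MA(1)
replaces AR(1) on x9/x10); E (x9, x10 ~ N(2,1)); F (x9 ~ Poisson(2),
x10 ~ Gamma(2,1)).

## Estimation and evaluation choices

Both propensity models are *deliberately misspecified* outside scenario A:
main effects of x1–x10 only. The baseline logit regresses the ever-treated
indicator on first-interval values; the Cox model uses counting-process rows
(one per at-risk subject-interval) with Efron tie handling, appropriate for
the heavy ties created by six coarse event times. Covariates with zero
variance in a replicate are dropped from a fit with a warning and contribute
zero to the linear predictor, which keeps thousand-replicate sweeps alive.

The treatment effect on a matched cohort is the weighted difference in means
of the outcome, computed as a weighted least-squares regression of outcome
on the treatment indicator over pooled pairs. Both members of a pair
contribute their outcome at the *pair's matching interval*: a control that
is treated later is thereby censored at its own treatment date, and for the
baseline matcher the never-treated control's outcome is read at its
partner's treatment interval (same calendar time). That calendar anchoring
is what leaves time-dependent drift unadjusted for the baseline method — the
mechanism behind its bias. We use the unadjusted single-regressor estimator
because it isolates matching quality; a covariate-adjusted variant would mix
matching performance with outcome-model extrapolation.

Across `M` replicates we report mean effect, mean model variance, mean SE,
mean bias `mean(1 - theta_m)`, percent bias, mean absolute bias, and
MSE/RMSE. The source material prints its "RMSE" formula without a square
root; we report `rmse = sqrt(mean((1 - theta_m)^2))` and also emit the raw
`mse` so either convention can be compared.

Balance reporting pools matched pairs across intervals ("aggregate at time
of treatment"), with a baseline scope (`at = "baseline"`) that re-reads
covariates at the first interval — used in particular for the time-dependent
covariates x4, x5, x9, x10. Classifications follow the usual rules of thumb:
standardized difference (x100) below 10 / 10–20 / above 20 and p-value above
0.10 / 0.05–0.10 / below 0.05 for balanced / weakly / strongly imbalanced.
The two-sample KS p-value is computed by a pooled-resampling bootstrap
(valid under ties, unlike the asymptotic null), implemented via multinomial
counts over the pooled support so that all resamples share one `rmultinom`
call; it is a pure function of `(data, seed, n_boot)`.

## The genetic search

`evolve_weights()` is a real-coded elitist genetic algorithm over the
diagonal of `W`: population 50, at most 30 generations, early stop after 4
generations without lexical improvement, weight domain `[0, 1000]`, initial
population = identity weights plus uniform draws (all configurable via
`ga_config()`). Generations are filled by tournament-selected parents passed
through uniform/boundary/non-uniform mutation, arithmetic and heuristic
crossover, cloning, and whole-vector resampling; the best-so-far candidate
is always retained, so the best loss is lexically non-decreasing by
construction. Inside the loss, KS bootstraps use 250 resamples with a fixed
sub-seed per risk set, making the loss a deterministic function of the
weights (final balance reporting uses 1,000). Scale invariance of the
distance in `W` means only relative weights matter.

One numerical point deserves emphasis. The matching matrix at each risk set
is x1–x10 at `t` plus the proxied propensity score. The Cox *linear
predictor* is an exact linear combination of those ten columns, so appending
it makes the covariance matrix singular and the appended column carries no
information after whitening. We therefore append the *hazard-scale* score
`exp(beta'x(t))` (rescaled by its maximum for stability; whitening absorbs
scale), which is how the time-dependent propensity score is defined as a
hazard in the risk-set matching literature and is non-linear in the
covariates. Sequential risk-set matching itself still uses linear-predictor
differences, where the distinction is irrelevant. The within-risk-set
covariance is ridge-regularized by `1e-8 * trace/K` when near-singular
(small risk sets late in follow-up).

The propensity-score column enters the distance by default but not the
balance loss (`include_ps = "distance"`), since balance is assessed on the
ten covariates; `"distance+loss"` and `"none"` are exposed for sensitivity
analysis, as is a mean-standardized-difference loss (`loss =
"mean-stddiff"`).

Genetic-matching results are sensitive to the search budget: with small
populations and few generations the balance p-values plateau quickly and the
matched cohorts stay close to unweighted Mahalanobis matching, whose bias in
these scenarios is materially larger than that of propensity-score
risk-set matching. Budget-reduced runs should be interpreted with that in
mind.

## Problem sizes used by the test suite and scripts

Simulating the full design (1,000 replicates of 1,000 subjects per scenario,
with a full genetic search per risk set) is a multi-day computation per
scenario. The package's own verification uses smaller, fixed problem sizes,
chosen once for turnaround:

- the fast test suite runs the bias pipelines at M = 200 replicates of
  n = 1,000 (baseline and time-dependent PS methods), balance at M = 100
  with 500 KS bootstrap resamples, and property tests on panels of a few
  hundred subjects;
- genetic-matching bias checks in the suite use M = 3 replicates of
  n = 1,000 with the reduced search budget (population 25, 15 generations);
  sample sizes below ~1,000 are avoided for this check because with strong
  covariate correlation the within-risk-set covariance becomes too noisy for
  Mahalanobis-type distances. `scripts/nightly.R` runs the same check at
  M = 50, which takes hours;
- `scripts/acceptance.R` recomputes the headline quantities at M = 100–200
  replicates of n = 1,000 with 1,000-resample KS bootstraps.

Monte Carlo noise at these sizes is a few percentage points of bias; the
qualitative ordering (baseline PS markedly biased everywhere, longitudinal
methods close to the truth except under strong correlation or non-normal
covariates) is stable.

## What the generator does and does not emulate

The simulated panels reproduce the statistical structure the estimators are
meant to confront: time-dependent confounding with autocorrelated covariate
drift, a non-linear non-additive assignment mechanism, mixed covariate
types, exchangeable cross-covariate correlation, and risk sets that shrink
as subjects are treated. They do not emulate real-world features such as
missing data, measurement error, informative censoring or dropout,
treatment-effect heterogeneity, survival/binary outcomes, or switchable
(time-varying) treatment regimes — the last two are explicit non-goals.
Passing tests therefore validate the estimators' comparative behaviour under
the modelled mechanisms, not their performance on any particular real
dataset.

## Known limitations

- The ever-treated calibration targets the overall rate; per-interval hazard
  shape is an emergent property, not controlled.
- Weighted lm standard errors treat tie/replacement weights as precision
  weights with row-count degrees of freedom; matching-robust (Abadie–Imbens)
  standard errors are out of scope.
- With `rho > 0`, the shared-factor construction adds persistence to
  time-dependent covariates; realized correlations differ from the latent
  `rho` for non-normal marginals.
- The genetic search optimizes within-risk-set marginal balance; it cannot
  directly target multivariate imbalance along outcome-relevant directions,
  and its effect-estimate quality depends on the search budget.
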