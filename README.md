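# longmatch

Monte Carlo simulation and matching estimators for **static treatments whose
assignment varies over time**. When patients can start a one-off treatment at
any of several follow-up intervals, covariates that drift during the waiting
period confound naive comparisons: matching ever-treated to never-treated
patients on baseline covariates ignores that drift and produces biased effect
estimates (including immortal-time bias). `longmatch` is for
biostatisticians and methodologists who want to study — or deploy — matching
estimators that respect treatment timing.

The package implements:

- **a panel-data generator** with time-dependent confounding: twelve mixed
  binary/continuous covariates (six time-dependent) drawn through a latent
  Gaussian copula with exchangeable correlation and AR(1)/MA(1) dynamics; a
  sequential logistic treatment-assignment model (non-linear, non-additive
  in the base case) with an intercept calibrated so one third of subjects
  are ever treated; and a continuous outcome
  `y_it = theta z_it + f(x_it) + e_it` with true effect `theta = 1`. Seven
  registered scenarios (`base`, `A`–`F`) vary functional form, correlation
  (rho = 0.2, 0.7), autocorrelation structure and covariate distributions
  (N(2,1), Poisson(2), Gamma(2,1)).
- **three matching estimators**, all 1:1 with replacement and ties
  (tied controls share weight 1/k):
  1. nearest-neighbour matching on a (deliberately misspecified) baseline
     logistic propensity score;
  2. sequential risk-set matching on the linear predictor `beta'x(t)` of a
     time-dependent Cox model for time to treatment — the "proxied"
     time-dependent propensity score, with the distance
     `|beta'x_i(t) - beta'x_j(t)|`;
  3. longitudinal genetic matching: within each risk set, 1:1 matching on a
     weighted generalized Mahalanobis distance
     `sqrt((x_i-x_j)' (S^{-1/2})' W (S^{-1/2}) (x_i-x_j))`
     whose diagonal weights `W` are chosen by an elitist real-coded genetic
     search maximizing lexically-ordered balance p-values (bootstrapped KS
     tests for continuous covariates, weighted paired t-tests for binary
     ones), with the hazard-scale propensity score appended as a matching
     variable.
- **diagnostics and metrics**: weighted standardized differences (x100),
  bootstrap KS and paired t balance tests with the conventional
  balanced / weakly / strongly imbalanced classifications, and replicate
  summaries (mean effect, mean variance/SE, mean and percent bias, mean
  absolute bias, MSE/RMSE).

See `vignettes/longitudinal-matching.Rmd` for the models, design decisions
and numerical choices.

## Worked example

```r
library(longmatch)

cfg   <- scenario_registry("base")
a0    <- calibrate_intercept(cfg, seed = 2024)   # -4.766: 1/3 ever treated
panel <- simulate_panel(cfg, seed = 1, alpha0 = a0)
panel
#> Longitudinal panel (scenario 'base'): 1000 subjects x 6 intervals
#>   newly treated per interval: 79 57 54 51 38 35
#>   ever treated: 314 (31.4%)

td     <- fit_td_cox(panel)          # proxied time-dependent propensity score
cohort <- match_td_ps(td, panel)     # sequential risk-set matching
estimate_effect(cohort, panel)
#> Treatment effect (td_ps): theta = 0.8749 (SE 0.1097), 314 treated

head(aggregate_balance(cohort, panel, n_boot = 1000, seed = 1), 4)
#>   covariate  std_diff   p_value     test  class_p
#> 1        x1 4.4526225 0.5888470 paired-t balanced
#> 2        x2 0.6370983 0.9357184 paired-t balanced
#> 3        x3 0.6399186 0.9357184 paired-t balanced
#> 4        x4 2.5692708 0.7477670 paired-t balanced
```

A single replicate is noisy; the Monte Carlo loop is one call:

```r
plan <- experiment_plan(scenarios = "base",
                        methods = c("baseline_ps", "td_ps"),
                        n_replicates = 50, master_seed = 2024)
res <- run_experiment(plan)
res$summary
#>   scenario      method m_replicates mean_effect ...   mean_bias  pct_bias      rmse
#> 1     base baseline_ps           50    1.345400 ... -0.34540014 34.540014 0.36602317
#> 2     base       td_ps           50    1.019979 ... -0.01997926  1.997926 0.09974632
```

Reading: over 50 replicates, baseline propensity-score matching overstates
the true effect of 1 by ~35% because it cannot see covariate drift between
baseline and treatment start, while sequential risk-set matching on the
time-dependent score is within 2% of the truth with a third of the RMSE.
Genetic matching is requested with `methods = "genmatch"` and tuned via
`ga_config()`; it is far more computationally intensive.

A thin command-line front end over the same functions ships in
`inst/scripts/longmatch.R`:

```sh
Rscript inst/scripts/longmatch.R simulate --scenario base \
    --replicates 200 --seed 7 --methods baseline_ps,td_ps --out out/
```

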