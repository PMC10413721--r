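Package: longmatch
Title: Longitudinal Matching for Time-Dependent Treatments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying longitudinal matching methods for static
    treatments whose assignment varies over time. Implements a Monte Carlo
    panel-data simulation framework with time-dependent confounding
    (autocorrelated and correlated mixed-type covariates, sequential
    logistic treatment assignment, a continuous outcome model), and three
    matching estimators: 1:1 nearest-neighbour matching on a baseline
    logistic propensity score, sequential risk-set matching on a
    time-dependent Cox proxied propensity score, and longitudinal genetic
    matching, which tunes a weighted generalized Mahalanobis distance by
    evolutionary search to maximize covariate balance within each risk set.
    Includes covariate-balance diagnostics (standardized differences,
    bootstrapped Kolmogorov-Smirnov and paired t tests) and replicate-level
    performance metrics (bias, variance, RMSE) for comparing estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
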