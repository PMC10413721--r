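## Covariate-balance diagnostics: standardized differences, bootstrapped
## two-sample KS tests, weighted paired t-tests, and pooled (aggregate)
## balance reports with the balanced / weakly / strongly imbalanced
## classification.

## run expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

## frequency-weight variance (matching-replacement weights act as counts)
weighted_var <- function(x, w) {
  sw <- sum(w)
  if (sw <= 1) return(0)
  m <- sum(w * x) / sw
  sum(w * (x - m)^2) / (sw - 1)
}

#' Absolute standardized difference (x100)
#'
#' `100 * |mean_t - mean_c| / sqrt((var_t + var_c) / 2)`, with
#' matching-replacement weights entering as frequency weights.
#'
#' @param x_treated,x_control covariate values in each arm.
#' @param w_treated,w_control non-negative weights (default 1).
#' @return Non-negative scalar on the conventional x100 scale; 0 when both
#'   arms are degenerate with equal means, `Inf` when the pooled SD is zero
#'   but means differ.
#' @export
standardized_difference <- function(x_treated, x_control,
                                    w_treated = NULL, w_control = NULL) {
  w_treated <- w_treated %||% rep(1, length(x_treated))
  w_control <- w_control %||% rep(1, length(x_control))
  mt <- weighted_mean(x_treated, w_treated)
  mc <- weighted_mean(x_control, w_control)
  pooled <- sqrt((weighted_var(x_treated, w_treated) +
                    weighted_var(x_control, w_control)) / 2)
  if (pooled == 0) return(if (isTRUE(all.equal(mt, mc))) 0 else Inf)
  100 * abs(mt - mc) / pooled
}

## weighted ECDF of sample (x, w) evaluated at points v
weighted_ecdf_at <- function(x, w, v) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  idx <- findInterval(v, x[o])
  c(0, cw)[idx + 1]
}

#' Weighted two-sample Kolmogorov-Smirnov statistic
#'
#' @param x1,x2 samples.
#' @param w1,w2 frequency weights (default 1).
#' @return Max absolute difference of the weighted ECDFs.
#' @export
ks_statistic <- function(x1, x2, w1 = NULL, w2 = NULL) {
  w1 <- w1 %||% rep(1, length(x1)); w2 <- w2 %||% rep(1, length(x2))
  v <- sort(unique(c(x1, x2)))
  max(abs(weighted_ecdf_at(x1, w1, v) - weighted_ecdf_at(x2, w2, v)))
}

## KS statistics for B pooled-null resamples. Drawing n iid values from the
## pooled weighted sample is equivalent to drawing multinomial counts over
## its distinct support, which lets all B resamples share one rmultinom
## call; D is then a difference of count-based ECDFs.
boot_ks_null <- function(v, pw, n1, n2, B) {
  o <- order(v)
  vs <- v[o]
  grp <- cumsum(c(TRUE, vs[-1] != vs[-length(vs)]))
  p_agg <- rowsum(pw[o], grp)
  C1 <- stats::rmultinom(B, n1, p_agg)
  C2 <- stats::rmultinom(B, n2, p_agg)
  F1 <- apply(C1, 2, cumsum) / n1
  F2 <- apply(C2, 2, cumsum) / n2
  apply(abs(F1 - F2), 2, max)
}

#' Bootstrap p-value for the two-sample KS test
#'
#' The observed weighted KS statistic is compared against a bootstrap null
#' in which both samples are redrawn from the pooled (weighted) empirical
#' distribution; resampling accommodates ties, for which the asymptotic KS
#' null is invalid.
#'
#' @param x_treated,x_control samples.
#' @param w_treated,w_control frequency weights (default 1).
#' @param n_boot number of null resamples (>= 100).
#' @param seed RNG seed; the p-value is a pure function of
#'   `(data, seed, n_boot)` and the caller's RNG stream is untouched.
#' @return Bootstrap p-value in `[0, 1]`.
#' @export
bootstrap_ks_p <- function(x_treated, x_control, w_treated = NULL,
                           w_control = NULL, n_boot = 1000, seed = 1L) {
  stopifnot(n_boot >= 100)
  w_treated <- w_treated %||% rep(1, length(x_treated))
  w_control <- w_control %||% rep(1, length(x_control))
  D <- ks_statistic(x_treated, x_control, w_treated, w_control)
  if (D == 0) return(1)
  v <- c(x_treated, x_control)
  pw <- c(w_treated, w_control); pw <- pw / sum(pw)
  n1 <- max(2L, as.integer(round(sum(w_treated))))
  n2 <- max(2L, as.integer(round(sum(w_control))))
  Db <- with_seed(seed, boot_ks_null(v, pw, n1, n2, n_boot))
  mean(Db >= D - 1e-12)
}

#' Weighted paired t-test p-value
#'
#' Tests whether within-pair differences have mean zero, with replacement
#' weights treated as frequency weights (effective sample size
#' `n = sum(w)`).
#'
#' @param diffs within-pair differences (treated minus matched control).
#' @param w pair weights.
#' @return Two-sided p-value; 1 if all differences are exactly zero, 0 if
#'   they are a nonzero constant.
#' @export
paired_t_p <- function(diffs, w = NULL) {
  w <- w %||% rep(1, length(diffs))
  n <- sum(w)
  m <- sum(w * diffs) / n
  v <- if (n > 1) sum(w * (diffs - m)^2) / (n - 1) else 0
  if (v == 0) return(if (isTRUE(all.equal(m, 0))) 1 else 0)
  tstat <- m / sqrt(v / n)
  2 * stats::pt(-abs(tstat), df = n - 1)
}

classify_p <- function(p) {
  ifelse(p > 0.10, "balanced",
         ifelse(p >= 0.05, "weakly imbalanced", "strongly imbalanced"))
}

classify_sd <- function(d) {
  ifelse(d < 10, "balanced",
         ifelse(d <= 20, "weakly imbalanced", "strongly imbalanced"))
}

#' Aggregate covariate balance of a matched cohort
#'
#' Pools matched pairs across intervals and, for each matching covariate,
#' compares treated and control values evaluated at each pair's matching
#' interval (`at = "treatment"`) or at the first interval
#' (`at = "baseline"`). Continuous covariates are tested with the
#' bootstrapped KS test, binary covariates with the weighted paired t-test;
#' both arms use the pair weights. Classifications follow the usual rules
#' of thumb: standardized difference below 10 balanced, 10-20 weakly
#' imbalanced, above 20 strongly imbalanced; p-value above 0.10 balanced,
#' 0.05-0.10 weakly imbalanced, below 0.05 strongly imbalanced.
#'
#' @param cohort a `matched_cohort`.
#' @param panel the underlying `panel_data`.
#' @param at scope: "treatment" (values at the pair's matching interval) or
#'   "baseline".
#' @param covariates covariate names to assess (default: the matching set).
#' @param n_boot,seed bootstrap controls for the KS p-values.
#' @return A `balance_report` data frame: covariate, scope, std_diff,
#'   p_value, test, class_sd, class_p.
#' @export
aggregate_balance <- function(cohort, panel, at = c("treatment", "baseline"),
                              covariates = panel$config$matching_covariates,
                              n_boot = 1000, seed = 1L) {
  at <- match.arg(at)
  stopifnot(nrow(cohort) > 0)
  iv <- if (at == "baseline") rep(1L, nrow(cohort)) else cohort$interval
  specs <- panel$config$covariates
  names(specs) <- vapply(specs, `[[`, "", "name")
  rows <- lapply(seq_along(covariates), function(j) {
    v <- covariates[j]
    xk <- panel$X[, v, ]
    xt <- xk[cbind(cohort$treated_id, iv)]
    xc <- xk[cbind(cohort$control_id, iv)]
    w <- cohort$weight
    sd_ <- standardized_difference(xt, xc, w, w)
    if (is_binary_spec(specs[[v]])) {
      p <- paired_t_p(xt - xc, w)
      test <- "paired-t"
    } else {
      p <- bootstrap_ks_p(xt, xc, w, w, n_boot = n_boot,
                          seed = replicate_seed(seed, j))
      test <- "boot-KS"
    }
    data.frame(covariate = v, scope = at, std_diff = sd_, p_value = p,
               test = test)
  })
  rep <- do.call(rbind, rows)
  rep$class_sd <- classify_sd(rep$std_diff)
  rep$class_p <- classify_p(rep$p_value)
  structure(rep, class = c("balance_report", "data.frame"),
            method = attr(cohort, "method"))
}

#' Pre-matching standardized differences
#'
#' The unmatched comparison pools, over every risk set, newly treated
#' subjects against all eligible controls at the same interval; used as the
#' reference point that matching is expected to improve on.
#'
#' @param panel a `panel_data`.
#' @param covariates covariate names (default: matching set).
#' @return Named vector of standardized differences (x100).
#' @export
unmatched_std_diff <- function(panel,
                               covariates = panel$config$matching_covariates) {
  rs <- build_risk_sets(panel)
  vapply(covariates, function(v) {
    xk <- panel$X[, v, ]
    xt <- unlist(lapply(rs, function(r) xk[r$treated, r$interval]))
    xc <- unlist(lapply(rs, function(r) xk[r$controls, r$interval]))
    standardized_difference(xt, xc)
  }, numeric(1))
}
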