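## Treatment-effect estimation on matched cohorts and Monte Carlo
## performance metrics across replicates.

#' Estimate the treatment effect on a matched cohort
#'
#' Weighted linear regression of the outcome on the treatment indicator
#' over the pooled matched pairs. Both members of a pair contribute their
#' outcome at the pair's matching interval, so a control later treated is
#' censored at its own treatment date: only its pre-treatment outcome is
#' used. The single-regressor weighted least-squares coefficient equals the
#' weighted difference in means.
#'
#' @param cohort a `matched_cohort`.
#' @param panel the underlying `panel_data`.
#' @return An `effect_estimate`: theta_hat, var_hat, se_hat, counts.
#' @export
estimate_effect <- function(cohort, panel) {
  if (is.null(cohort) || nrow(cohort) == 0)
    stop("cannot estimate an effect from an empty matched cohort")
  yt <- panel$y[cbind(cohort$treated_id, cohort$interval)]
  yc <- panel$y[cbind(cohort$control_id, cohort$interval)]
  df <- data.frame(y = c(yt, yc),
                   z = rep(c(1, 0), each = nrow(cohort)),
                   w = rep(cohort$weight, 2))
  fit <- stats::lm(y ~ z, data = df, weights = w)
  theta <- unname(stats::coef(fit)["z"])
  v <- stats::vcov(fit)["z", "z"]
  structure(list(theta_hat = theta, var_hat = v, se_hat = sqrt(v),
                 n_treated = length(unique(cohort$treated_id)),
                 n_subjects = length(unique(c(cohort$treated_id,
                                              cohort$control_id))),
                 n_unmatched = length(attr(cohort, "unmatched")),
                 method = attr(cohort, "method"),
                 replicate_id = attr(cohort, "replicate_id")),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Treatment effect (%s): theta = %.4f (SE %.4f), %d treated%s\n",
              x$method, x$theta_hat, x$se_hat, x$n_treated,
              if (x$n_unmatched > 0)
                sprintf(", %d unmatched", x$n_unmatched) else ""))
  invisible(x)
}

#' Summarize effect estimates over Monte Carlo replicates
#'
#' Computes, per method: mean effect `(1/M) sum theta_m`; mean variance
#' `(1/M) sum S_m^2`; mean SE; mean bias `(1/M) sum (theta_true - theta_m)`;
#' percent bias `100 |mean bias| / theta_true`; mean absolute bias; MSE
#' `(1/M) sum (theta_true - theta_m)^2` and RMSE (its square root).
#'
#' @param estimates list of `effect_estimate` objects (possibly mixed
#'   methods) or a data frame with columns `method`, `theta_hat`,
#'   `var_hat`, `se_hat`.
#' @param theta_true true effect (default 1).
#' @return A `sim_summary` data frame, one row per method.
#' @export
summarize_estimates <- function(estimates, theta_true = 1) {
  if (!is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(method = e$method, theta_hat = e$theta_hat,
                 var_hat = e$var_hat, se_hat = e$se_hat)))
  }
  stopifnot(nrow(estimates) >= 1)
  rows <- lapply(split(estimates, estimates$method), function(d) {
    err <- theta_true - d$theta_hat
    mse <- mean(err^2)
    data.frame(method = d$method[1], m_replicates = nrow(d),
               mean_effect = mean(d$theta_hat),
               mean_variance = mean(d$var_hat),
               mean_se = mean(d$se_hat),
               mean_bias = mean(err),
               pct_bias = 100 * abs(mean(err)) / abs(theta_true),
               mean_abs_bias = mean(abs(err)),
               mse = mse, rmse = sqrt(mse))
  })
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("sim_summary", "data.frame"),
            theta_true = theta_true)
}

#' @export
print.sim_summary <- function(x, digits = 4, ...) {
  cat("Monte Carlo performance summary (theta_true =",
      attr(x, "theta_true"), ")\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
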