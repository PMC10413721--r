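## Propensity models: a deliberately misspecified baseline logistic PS
## (ever-treated on baseline covariate values, main effects only) and a
## time-dependent Cox model whose linear predictor serves as a proxied
## time-dependent propensity score.

## drop covariates with zero variance, warning once
nondegenerate <- function(xmat, context) {
  v <- apply(xmat, 2, stats::var)
  drop <- colnames(xmat)[v <= 0 | !is.finite(v)]
  if (length(drop))
    warning(context, ": dropping degenerate covariate(s) ",
            paste(drop, collapse = ", "), call. = FALSE)
  setdiff(colnames(xmat), drop)
}

#' Fit the baseline logistic propensity score
#'
#' Regresses the ever-treated indicator on main effects of the ten matching
#' covariates at their baseline (first-interval) values. This model ignores
#' treatment timing and any non-linear or interaction terms in the true
#' assignment model; its misspecification is intentional.
#'
#' @param panel a `panel_data` object.
#' @return A `baseline_ps_model` with `coefficients`, per-subject
#'   `fitted` probabilities, and the names of any `dropped` covariates.
#' @export
fit_baseline_ps <- function(panel) {
  X0 <- x_at(panel$X, 1)[, panel$config$matching_covariates, drop = FALSE]
  ever <- as.integer(!is.na(panel$treat_interval))
  if (sum(ever) == 0 || sum(ever) == length(ever))
    stop("baseline PS needs at least one ever-treated and one never-treated subject")
  keep <- nondegenerate(X0, "baseline PS")
  df <- data.frame(X0[, keep, drop = FALSE])
  df$.z <- ever
  fit <- stats::glm(.z ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("baseline logistic PS did not converge")
  if (any(abs(stats::coef(fit)[-1]) > 30, na.rm = TRUE))
    stop("baseline logistic PS shows signs of perfect separation")
  beta <- stats::setNames(rep(0, length(colnames(X0))), colnames(X0))
  cf <- stats::coef(fit)
  beta[keep] <- cf[make.names(keep)]
  structure(list(intercept = unname(cf[1]), coefficients = beta,
                 fitted = unname(stats::fitted(fit)),
                 dropped = setdiff(colnames(X0), keep),
                 converged = fit$converged),
            class = "baseline_ps_model")
}

#' @export
print.baseline_ps_model <- function(x, ...) {
  cat("Baseline logistic propensity model (ever-treated ~ baseline covariates)\n")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  invisible(x)
}

## counting-process layout: one row per subject-interval while at risk,
## event = treatment at the end of that interval
counting_process_data <- function(panel) {
  X <- panel$X
  ti <- panel$treat_interval
  n <- dim(X)[1]; T <- dim(X)[3]
  vars <- panel$config$matching_covariates
  last <- ifelse(is.na(ti), T, ti)
  id <- rep(seq_len(n), last)
  t_idx <- sequence(last)
  out <- data.frame(id = id, start = t_idx - 1, stop = t_idx,
                    event = as.integer(!is.na(ti[id]) & ti[id] == t_idx))
  for (v in vars) out[[v]] <- X[, v, ][cbind(id, t_idx)]
  out
}

#' Fit the time-dependent Cox propensity model
#'
#' Fits a Cox proportional-hazards model for time to treatment with the ten
#' matching covariates as (possibly time-dependent) main effects, in
#' counting-process form with one row per at-risk subject-interval. Ties at
#' the coarse interval-valued event times are handled with the Efron
#' approximation. The fitted linear predictor `beta' x(t)` is the proxied
#' time-dependent propensity score used for risk-set matching; the baseline
#' hazard cancels from all score differences.
#'
#' @param panel a `panel_data` object.
#' @return A `td_ps_model` with `coefficients` (zero for any dropped
#'   degenerate covariate) and fit diagnostics.
#' @export
fit_td_cox <- function(panel) {
  cp <- counting_process_data(panel)
  if (sum(cp$event) == 0) stop("no treatment events; cannot fit Cox model")
  vars <- panel$config$matching_covariates
  keep <- nondegenerate(as.matrix(cp[vars]), "time-dependent Cox")
  f <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                               paste(keep, collapse = " + ")))
  fit <- survival::coxph(f, data = cp, ties = "efron")
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 30))
    stop("Cox partial likelihood appears monotone (unbounded coefficient); ",
         "treatment may be perfectly ordered by a covariate")
  beta <- stats::setNames(rep(0, length(vars)), vars)
  beta[keep] <- cf[keep]
  structure(list(coefficients = beta, dropped = setdiff(vars, keep),
                 loglik = fit$loglik, iter = fit$iter),
            class = "td_ps_model")
}

#' @export
print.td_ps_model <- function(x, ...) {
  cat("Time-dependent Cox propensity model (proxied PS)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Linear predictor of a propensity model
#'
#' @param model a `td_ps_model` (or any object with a `coefficients`
#'   vector).
#' @param x covariate vector or matrix with columns matching the model
#'   coefficients.
#' @return Numeric score(s) `beta' x`; matching distances are absolute
#'   differences of these scores, so any additive constant is irrelevant.
#' @export
linear_predictor <- function(model, x) {
  beta <- model$coefficients
  if (is.null(dim(x))) {
    stopifnot(length(x) == length(beta))
    return(sum(beta * x))
  }
  drop(x[, names(beta), drop = FALSE] %*% beta)
}

#' Proxied propensity scores for every subject and interval
#'
#' @param model a fitted `td_ps_model`.
#' @param panel the panel the model was fitted on (or a compatible one).
#' @return `n x T` matrix of Cox linear predictors.
#' @export
td_linear_predictor <- function(model, panel) {
  T <- dim(panel$X)[3]
  vapply(seq_len(T), function(t)
    linear_predictor(model, x_at(panel$X, t)), numeric(dim(panel$X)[1]))
}
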