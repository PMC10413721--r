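#' Effect-size coefficients for the simulation models
#'
#' Low, medium and high log-scale effects used in both the treatment
#' assignment and outcome models. Defaults are log(1.25), log(1.5) and
#' log(1.75).
#'
#' @param L,M,H log odds / log effect sizes.
#' @return Named list of coefficients.
#' @export
coefficient_set <- function(L = log(1.25), M = log(1.5), H = log(1.75)) {
  stopifnot(is.finite(L), is.finite(M), is.finite(H))
  list(L = L, M = M, H = H)
}

#' Describe one simulated covariate
#'
#' @param name covariate identifier (e.g. "x1").
#' @param dist marginal distribution: "bernoulli", "normal", "poisson" or
#'   "gamma".
#' @param par named parameter vector for the marginal (`p`; `mu`,`sd`;
#'   `lambda`; `shape`,`rate`).
#' @param time_dependent does the value change across intervals?
#' @param process temporal process for time-dependent covariates: "none",
#'   "iid" (independent redraw each interval), "ar1" or "ma1" on the latent
#'   normal scale.
#' @param in_treatment,in_outcome role flags: does the covariate enter the
#'   true treatment and/or outcome model?
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(name, dist, par, time_dependent = FALSE,
                           process = if (time_dependent) "iid" else "none",
                           in_treatment = TRUE, in_outcome = TRUE) {
  dist <- match.arg(dist, c("bernoulli", "normal", "poisson", "gamma"))
  process <- match.arg(process, c("none", "iid", "ar1", "ma1"))
  if (!time_dependent && process != "none")
    stop("time-invariant covariate '", name, "' must have process = 'none'")
  if (time_dependent && process == "none")
    stop("time-dependent covariate '", name, "' needs a temporal process")
  structure(list(name = name, dist = dist, par = par,
                 time_dependent = time_dependent, process = process,
                 in_treatment = in_treatment, in_outcome = in_outcome),
            class = "covariate_spec")
}

is_binary_spec <- function(spec) spec$dist == "bernoulli"

## model terms: product of covariates raised to powers, times a coefficient
## (one of the labels "L","M","H" or a bare number)
model_term <- function(coef, vars, powers = rep(1, length(vars))) {
  stopifnot(length(vars) == length(powers))
  list(vars = vars, powers = powers, coef = coef)
}

coef_value <- function(coef, coefs) {
  if (is.character(coef)) {
    if (!coef %in% names(coefs)) stop("unknown coefficient label: ", coef)
    coefs[[coef]]
  } else as.numeric(coef)
}

## evaluate a list of model terms on an n x K covariate matrix
eval_terms <- function(terms, xmat, coefs) {
  lp <- numeric(nrow(xmat))
  for (tm in terms) {
    miss <- setdiff(tm$vars, colnames(xmat))
    if (length(miss))
      stop("model references unknown covariate(s): ", paste(miss, collapse = ", "))
    v <- rep(1, nrow(xmat))
    for (j in seq_along(tm$vars)) v <- v * xmat[, tm$vars[j]]^tm$powers[j]
    lp <- lp + coef_value(tm$coef, coefs) * v
  }
  lp
}

base_covariate_set <- function() {
  bern <- function(name, td = FALSE, treat = TRUE, outc = TRUE)
    covariate_spec(name, "bernoulli", c(p = 0.5), time_dependent = td,
                   in_treatment = treat, in_outcome = outc)
  norm <- function(name, mu = 0, sd = 1, td = FALSE, process = if (td) "ar1" else "none",
                   treat = TRUE, outc = TRUE)
    covariate_spec(name, "normal", c(mu = mu, sd = sd), time_dependent = td,
                   process = process, in_treatment = treat, in_outcome = outc)
  list(bern("x1"), bern("x2"), bern("x3"),
       bern("x4", td = TRUE, outc = FALSE),
       bern("x5", td = TRUE),
       norm("x6"), norm("x7"), norm("x8"),
       norm("x9", td = TRUE, treat = TRUE, outc = FALSE),
       norm("x10", td = TRUE),
       bern("x11", td = TRUE, treat = FALSE),
       norm("x12", td = TRUE, treat = FALSE))
}

base_treatment_terms <- function() {
  list(model_term("L", "x1"), model_term("M", "x2"), model_term("H", "x3"),
       model_term("L", "x4"), model_term("H", "x5"),
       model_term("M", c("x4", "x5")),
       model_term("L", "x6"), model_term("M", "x7"),
       model_term("L", "x7", 2),
       model_term("H", "x8"),
       model_term("L", "x9", 2),
       model_term("M", c("x6", "x9"), c(1, 2)),
       model_term("H", "x10"))
}

linear_treatment_terms <- function() {
  list(model_term("L", "x1"), model_term("M", "x2"), model_term("H", "x3"),
       model_term("L", "x4"), model_term("H", "x5"),
       model_term("L", "x6"), model_term("M", "x7"), model_term("H", "x8"),
       model_term("L", "x9"), model_term("H", "x10"))
}

outcome_terms <- function() {
  list(model_term("L", "x1"), model_term("M", "x2"), model_term("H", "x3"),
       model_term("H", "x5"),
       model_term("L", "x6"), model_term("M", "x7"), model_term("H", "x8"),
       model_term("H", "x10"),
       model_term("L", "x11"), model_term("L", "x12"))
}

#' Build a simulation scenario configuration
#'
#' Assembles the full description of one Monte Carlo scenario: covariate
#' marginals and temporal processes, latent pairwise correlation, the true
#' treatment-assignment and outcome models, and simulation sizes.
#'
#' @param scenario_id identifier string.
#' @param covariates list of [covariate_spec()] objects (exactly 6 binary
#'   and 6 continuous).
#' @param pairwise_rho latent exchangeable correlation across covariates,
#'   in `[0, 1)`, induced through a Gaussian copula.
#' @param treatment_model,outcome_model term lists for the true models.
#' @param coefficients a [coefficient_set()].
#' @param theta_true true additive treatment effect on the outcome scale.
#' @param alpha_0_treat treatment-model intercept; `NA` until calibrated
#'   with [calibrate_intercept()].
#' @param n_subjects,n_intervals,n_replicates simulation sizes.
#' @param ar_phi,ma_theta AR(1)/MA(1) parameters on the latent scale.
#' @param noise_sigma SD of the additive outcome noise.
#' @param master_seed default seed for replicate streams.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario_id = "custom",
                            covariates = base_covariate_set(),
                            pairwise_rho = 0,
                            treatment_model = base_treatment_terms(),
                            outcome_model = outcome_terms(),
                            coefficients = coefficient_set(),
                            theta_true = 1,
                            alpha_0_treat = NA_real_,
                            n_subjects = 1000L,
                            n_intervals = 6L,
                            n_replicates = 1000L,
                            ar_phi = 0.5,
                            ma_theta = 0.5,
                            noise_sigma = 1,
                            master_seed = 1L) {
  if (pairwise_rho < 0 || pairwise_rho >= 1)
    stop("pairwise_rho must lie in [0, 1)")
  nbin <- sum(vapply(covariates, is_binary_spec, TRUE))
  ncont <- length(covariates) - nbin
  if (nbin != 6L || ncont != 6L)
    stop("a scenario requires exactly 6 binary and 6 continuous covariates (got ",
         nbin, " binary, ", ncont, " continuous)")
  if (abs(ar_phi) >= 1) stop("ar_phi must satisfy |phi| < 1")
  nms <- vapply(covariates, `[[`, "", "name")
  cfg <- structure(list(
    scenario_id = scenario_id, covariates = covariates,
    pairwise_rho = pairwise_rho,
    treatment_model = treatment_model, outcome_model = outcome_model,
    coefficients = coefficients, theta_true = theta_true,
    alpha_0_treat = alpha_0_treat,
    n_subjects = as.integer(n_subjects), n_intervals = as.integer(n_intervals),
    n_replicates = as.integer(n_replicates),
    ar_phi = ar_phi, ma_theta = ma_theta, noise_sigma = noise_sigma,
    master_seed = as.integer(master_seed),
    matching_covariates = intersect(paste0("x", 1:10), nms)),
    class = "scenario_config")
  cfg
}

#' Retrieve a registered simulation scenario
#'
#' The registry holds the base case plus scenarios A-F: A uses a
#' linear-additive treatment model (correct functional form for the
#' propensity models); B and C add weak (0.2) and strong (0.7) latent
#' pairwise correlation; D swaps the AR(1) process on x9/x10 for MA(1);
#' E draws x9, x10 from N(2,1); F draws x9 from Poisson(2) and x10 from
#' Gamma(2,1).
#'
#' @param scenario_id one of "base", "A", "B", "C", "D", "E", "F".
#' @param ... overrides passed on to [scenario_config()] (e.g.
#'   `n_subjects`, `master_seed`).
#' @return A `scenario_config`.
#' @export
scenario_registry <- function(scenario_id, ...) {
  ids <- c("base", "A", "B", "C", "D", "E", "F")
  if (!scenario_id %in% ids)
    stop("unknown scenario '", scenario_id, "'; valid ids: ",
         paste(ids, collapse = ", "))
  covs <- base_covariate_set()
  nm <- vapply(covs, `[[`, "", "name")
  args <- list(scenario_id = scenario_id, covariates = covs)
  if (scenario_id == "A") args$treatment_model <- linear_treatment_terms()
  if (scenario_id == "B") args$pairwise_rho <- 0.2
  if (scenario_id == "C") args$pairwise_rho <- 0.7
  if (scenario_id == "D") {
    for (k in which(nm %in% c("x9", "x10"))) covs[[k]]$process <- "ma1"
    args$covariates <- covs
  }
  if (scenario_id == "E") {
    for (k in which(nm %in% c("x9", "x10"))) covs[[k]]$par <- c(mu = 2, sd = 1)
    args$covariates <- covs
  }
  if (scenario_id == "F") {
    k9 <- which(nm == "x9"); k10 <- which(nm == "x10")
    covs[[k9]]$dist <- "poisson"; covs[[k9]]$par <- c(lambda = 2)
    covs[[k10]]$dist <- "gamma";  covs[[k10]]$par <- c(shape = 2, rate = 1)
    args$covariates <- covs
  }
  do.call(scenario_config, c(args, list(...)))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario '", x$scenario_id, "'\n", sep = "")
  cat("  subjects:", x$n_subjects, " intervals:", x$n_intervals,
      " replicates:", x$n_replicates, "\n")
  cat("  pairwise rho:", x$pairwise_rho,
      " ar_phi:", x$ar_phi, " ma_theta:", x$ma_theta,
      " noise sd:", x$noise_sigma, "\n")
  td <- vapply(x$covariates, `[[`, TRUE, "time_dependent")
  cat("  covariates:", paste(vapply(x$covariates, `[[`, "", "name"),
                             collapse = " "), "\n")
  cat("  time-dependent:", paste(vapply(x$covariates[td], `[[`, "", "name"),
                                 collapse = " "), "\n")
  cat("  treatment intercept:",
      if (is.na(x$alpha_0_treat)) "uncalibrated" else
        format(x$alpha_0_treat, digits = 4), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
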