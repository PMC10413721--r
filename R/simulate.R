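## Panel data generation: latent Gaussian copula covariate paths, sequential
## logistic treatment assignment, continuous outcome model.

#' Deterministic per-replicate seed stream
#'
#' @param master_seed experiment-level seed.
#' @param r replicate index (>= 1).
#' @return An integer seed, a pure function of (master_seed, r).
#' @export
replicate_seed <- function(master_seed, r) {
  v <- (as.numeric(master_seed %% 2147483647L) * 48271 +
          as.numeric(r) * 104729) %% 2147483647
  as.integer(v) + 1L
}

## latent N(0,1) path for one covariate: n x T matrix with the configured
## temporal process and stationary unit marginal variance
draw_latent_path <- function(spec, n, T, ar_phi, ma_theta) {
  switch(spec$process,
    none = matrix(rnorm(n), n, T),
    iid  = matrix(rnorm(n * T), n, T),
    ar1  = {
      V <- matrix(0, n, T)
      V[, 1] <- rnorm(n)
      if (T > 1) {
        innov_sd <- sqrt(1 - ar_phi^2)
        for (t in 2:T) V[, t] <- ar_phi * V[, t - 1] + rnorm(n, sd = innov_sd)
      }
      V
    },
    ma1  = {
      eps <- matrix(rnorm(n * (T + 1)), n, T + 1)
      sc <- sqrt(1 + ma_theta^2)
      (eps[, 2:(T + 1), drop = FALSE] + ma_theta * eps[, 1:T, drop = FALSE]) / sc
    },
    stop("unknown temporal process: ", spec$process))
}

## map a latent standard-normal matrix to the configured marginal
transform_marginal <- function(Z, spec) {
  p <- spec$par
  switch(spec$dist,
    bernoulli = (Z > stats::qnorm(1 - p[["p"]])) + 0,
    normal    = p[["mu"]] + p[["sd"]] * Z,
    poisson   = stats::qpois(stats::pnorm(Z), p[["lambda"]]),
    gamma     = stats::qgamma(stats::pnorm(Z), shape = p[["shape"]],
                              rate = p[["rate"]]),
    stop("unknown marginal distribution: ", spec$dist))
}

## covariate array draw, assumes the RNG state is already set
draw_covariate_paths_ <- function(config, n = config$n_subjects) {
  T <- config$n_intervals
  K <- length(config$covariates)
  rho <- config$pairwise_rho
  U <- if (rho > 0) rnorm(n) else NULL
  X <- array(NA_real_, c(n, K, T),
             dimnames = list(NULL, vapply(config$covariates, `[[`, "", "name"),
                             NULL))
  for (k in seq_len(K)) {
    spec <- config$covariates[[k]]
    V <- draw_latent_path(spec, n, T, config$ar_phi, config$ma_theta)
    Z <- if (rho > 0) sqrt(rho) * U + sqrt(1 - rho) * V else V
    X[, k, ] <- transform_marginal(Z, spec)
  }
  X
}

#' Draw covariate paths for one panel
#'
#' Generates the subject-by-covariate-by-interval array. Exchangeable
#' cross-covariate correlation is induced on a latent multivariate-normal
#' scale through a subject-level shared factor (Gaussian copula): binary
#' covariates arise by thresholding the latent normal at the appropriate
#' quantile, Poisson and gamma covariates by inverse-CDF transform.
#' Time-dependent covariates follow the configured latent process (iid
#' redraw, AR(1) or MA(1)) with stationary unit variance, so their marginal
#' distribution is preserved across intervals.
#'
#' @param config a [scenario_config()].
#' @param n number of subjects (defaults to `config$n_subjects`).
#' @param seed integer RNG seed.
#' @return Array of dim `c(n, K, T)` with covariate names on dimension 2.
#' @export
draw_covariate_paths <- function(config, n = config$n_subjects, seed) {
  stopifnot(inherits(config, "scenario_config"), n >= 1)
  set.seed(seed)
  draw_covariate_paths_(config, n)
}

## n x K covariate matrix at interval t, preserving column names
x_at <- function(X, t) {
  m <- X[, , t, drop = FALSE]
  dim(m) <- dim(X)[1:2]
  colnames(m) <- dimnames(X)[[2]]
  m
}

## sequential assignment given pre-drawn uniforms; pure function
assign_treatment_ <- function(X, u, config, alpha0) {
  n <- dim(X)[1]; T <- dim(X)[3]
  coefs <- config$coefficients
  ti <- rep(NA_integer_, n)
  for (t in seq_len(T)) {
    at_risk <- is.na(ti)
    if (!any(at_risk)) break
    lp <- alpha0 + eval_terms(config$treatment_model, x_at(X, t), coefs)
    if (any(!is.finite(lp[at_risk]))) {
      bad <- which(at_risk & !is.finite(lp))[1]
      stop("non-finite treatment linear predictor for subject ", bad,
           " at interval ", t)
    }
    newly <- at_risk & (u[, t] < stats::plogis(lp))
    ti[newly] <- t
  }
  ti
}

#' Assign treatment intervals sequentially
#'
#' For each interval in time order, every not-yet-treated subject receives
#' treatment with probability `plogis(alpha0 + linear predictor)` evaluated
#' on the current covariate values; treated subjects leave the risk pool, so
#' each subject is treated at most once and assignment never looks at future
#' covariate values.
#'
#' @param X covariate array from [draw_covariate_paths()].
#' @param config scenario configuration.
#' @param seed integer RNG seed.
#' @param alpha0 treatment-model intercept (defaults to the calibrated value
#'   stored in `config`).
#' @return Integer vector of treatment intervals (`NA` = never treated).
#' @export
assign_treatment <- function(X, config, seed, alpha0 = config$alpha_0_treat) {
  if (is.na(alpha0)) stop("alpha_0_treat is not set; run calibrate_intercept()")
  set.seed(seed)
  u <- matrix(runif(dim(X)[1] * dim(X)[3]), dim(X)[1], dim(X)[3])
  assign_treatment_(X, u, config, alpha0)
}

generate_outcome_ <- function(X, ti, eps, config) {
  n <- dim(X)[1]; T <- dim(X)[3]
  coefs <- config$coefficients
  y <- matrix(NA_real_, n, T)
  for (t in seq_len(T)) {
    z <- as.numeric(!is.na(ti) & ti <= t)
    y[, t] <- config$theta_true * z +
      eval_terms(config$outcome_model, x_at(X, t), coefs) + eps[, t]
  }
  y
}

#' Generate the continuous outcome panel
#'
#' `y[i, t] = theta_true * z[i, t] + outcome-model terms at t + N(0, sigma^2)`
#' where `z[i, t] = 1` once subject i has been treated at or before t.
#'
#' @param X covariate array.
#' @param treat_interval integer vector from [assign_treatment()].
#' @param config scenario configuration.
#' @param seed integer RNG seed for the noise draws.
#' @return `n x T` outcome matrix.
#' @export
generate_outcome <- function(X, treat_interval, config, seed) {
  set.seed(seed)
  n <- dim(X)[1]; T <- dim(X)[3]
  eps <- matrix(rnorm(n * T, sd = config$noise_sigma), n, T)
  generate_outcome_(X, treat_interval, eps, config)
}

## one full draw of randomness for a replicate, in a fixed order so that
## treatment probabilities can be re-evaluated under different intercepts
## with common random numbers
draw_sim_parts <- function(config, n = config$n_subjects) {
  X <- draw_covariate_paths_(config, n)
  T <- config$n_intervals
  u <- matrix(runif(n * T), n, T)
  eps <- matrix(rnorm(n * T, sd = config$noise_sigma), n, T)
  list(X = X, u = u, eps = eps)
}

#' Simulate one longitudinal panel dataset
#'
#' Draws covariate paths, assigns treatment sequentially, and generates
#' outcomes, all from a single seed.
#'
#' @param config a [scenario_config()] with a calibrated intercept (or
#'   supply `alpha0`).
#' @param seed integer seed; the panel is a pure function of
#'   `(config, seed)`.
#' @param alpha0 treatment-model intercept override.
#' @param replicate_id optional replicate label stored on the object.
#' @return A `panel_data` object: list with covariate array `X`
#'   (`n x K x T`), `treat_interval` (integer, `NA` = never treated),
#'   outcome matrix `y` (`n x T`), and the generating `config`.
#' @export
simulate_panel <- function(config, seed, alpha0 = config$alpha_0_treat,
                           replicate_id = NA_integer_) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.na(alpha0))
    stop("alpha_0_treat is not set; run calibrate_intercept() first")
  set.seed(seed)
  parts <- draw_sim_parts(config)
  ti <- assign_treatment_(parts$X, parts$u, config, alpha0)
  y <- generate_outcome_(parts$X, ti, parts$eps, config)
  structure(list(X = parts$X, treat_interval = ti, y = y, config = config,
                 alpha0 = alpha0, seed = seed, replicate_id = replicate_id),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  n <- dim(x$X)[1]; T <- dim(x$X)[3]
  cat("Longitudinal panel (scenario '", x$config$scenario_id, "'): ",
      n, " subjects x ", T, " intervals\n", sep = "")
  nt <- table(factor(x$treat_interval, levels = seq_len(T)))
  cat("  newly treated per interval:", paste(nt, collapse = " "), "\n")
  cat("  ever treated:", sum(!is.na(x$treat_interval)),
      sprintf("(%.1f%%)\n", 100 * mean(!is.na(x$treat_interval))))
  invisible(x)
}

#' Calibrate the treatment-model intercept
#'
#' Finds `alpha_0_treat` such that the expected fraction of ever-treated
#' subjects matches `target_rate` (1/3 in the base case). The ever-treated
#' rate is monotone increasing in the intercept, so the search is a
#' bisection; pilot covariate paths and assignment uniforms are drawn once
#' and reused across intercept evaluations (common random numbers), making
#' the objective deterministic and monotone.
#'
#' @param config scenario configuration.
#' @param target_rate desired ever-treated fraction, in (0, 1).
#' @param tol tolerance on the achieved pilot rate.
#' @param pilot_reps,pilot_n number and size of pilot panels.
#' @param seed seed for the pilot draws.
#' @param bracket initial intercept bracket.
#' @param max_iter bisection iteration cap.
#' @return The calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(config, target_rate = 1/3, tol = 0.005,
                                pilot_reps = 20, pilot_n = NULL, seed = 1L,
                                bracket = c(-30, 10), max_iter = 80) {
  stopifnot(target_rate > 0, target_rate < 1)
  if (target_rate <= tol || target_rate >= 1 - tol)
    stop("target_rate ", target_rate, " is degenerate relative to the ",
         "calibration tolerance ", tol)
  pilot_n <- pilot_n %||% config$n_subjects
  parts <- lapply(seq_len(pilot_reps), function(r) {
    set.seed(replicate_seed(seed, r))
    draw_sim_parts(config, pilot_n)
  })
  rate <- function(a0) {
    mean(vapply(parts, function(p)
      mean(!is.na(assign_treatment_(p$X, p$u, config, a0))), numeric(1)))
  }
  lo <- bracket[1]; hi <- bracket[2]
  rlo <- rate(lo); rhi <- rate(hi)
  if (rlo > target_rate || rhi < target_rate)
    stop(sprintf(
      "calibration target %.4f unreachable: rates at bracket [%g, %g] are [%.4f, %.4f]",
      target_rate, lo, hi, rlo, rhi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    rm <- rate(mid)
    if (abs(rm - target_rate) <= tol) return(mid)
    if (rm < target_rate) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "intercept calibration did not converge: bracket [%g, %g], rates [%.4f, %.4f]",
    lo, hi, rate(lo), rate(hi)))
}

#' Generate a stream of replicate panels
#'
#' Replicate `r` uses seed `replicate_seed(master_seed, r)` and is therefore
#' reproducible in isolation.
#'
#' @param config scenario configuration.
#' @param n_replicates number of panels.
#' @param master_seed experiment seed (defaults to `config$master_seed`).
#' @param alpha0 intercept override.
#' @param FUN optional function applied to each panel; with the default the
#'   panels themselves are returned.
#' @return List of `FUN(panel)` results, length `n_replicates`.
#' @export
generate_replicates <- function(config, n_replicates = config$n_replicates,
                                master_seed = config$master_seed,
                                alpha0 = config$alpha_0_treat,
                                FUN = identity) {
  lapply(seq_len(n_replicates), function(r) {
    FUN(simulate_panel(config, seed = replicate_seed(master_seed, r),
                       alpha0 = alpha0, replicate_id = r))
  })
}
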