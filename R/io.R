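## Plain-text interchange: long-format panel CSV, matched-cohort CSV, and
## YAML scenario configurations.

#' Write a panel dataset to long-format CSV
#'
#' Columns: replicate, subject, interval, one column per covariate, z
#' (treated at or before the interval), y, treat_interval (empty when never
#' treated).
#'
#' @param panel a `panel_data`.
#' @param path output file; a ".gz" suffix writes gzip-compressed.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  n <- dim(panel$X)[1]; T <- dim(panel$X)[3]
  nms <- dimnames(panel$X)[[2]]
  ti <- panel$treat_interval
  rows <- do.call(rbind, lapply(seq_len(T), function(t) {
    d <- data.frame(replicate = panel$replicate_id, subject = seq_len(n),
                    interval = t)
    for (v in nms) d[[v]] <- panel$X[, v, t]
    d$z <- as.integer(!is.na(ti) & ti <= t)
    d$y <- panel$y[, t]
    d$treat_interval <- ti
    d
  }))
  rows <- rows[order(rows$subject, rows$interval), ]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read a long-format panel CSV
#'
#' Inverse of [write_panel()]. A `scenario_config` must be supplied (or a
#' compatible one constructed) so covariate types and models are known.
#'
#' @param path CSV file as written by [write_panel()].
#' @param config the generating `scenario_config`.
#' @return A `panel_data` object.
#' @export
read_panel <- function(path, config) {
  d <- utils::read.csv(path)
  d <- d[order(d$subject, d$interval), ]
  subs <- sort(unique(d$subject))
  ints <- sort(unique(d$interval))
  n <- length(subs); T <- length(ints)
  nms <- vapply(config$covariates, `[[`, "", "name")
  X <- array(NA_real_, c(n, length(nms), T), dimnames = list(NULL, nms, NULL))
  y <- matrix(NA_real_, n, T)
  for (t in seq_len(T)) {
    dt <- d[d$interval == ints[t], ]
    dt <- dt[match(subs, dt$subject), ]
    for (v in nms) X[, v, t] <- dt[[v]]
    y[, t] <- dt$y
  }
  d1 <- d[d$interval == ints[1], ]
  d1 <- d1[match(subs, d1$subject), ]
  ti <- as.integer(d1$treat_interval)
  structure(list(X = X, treat_interval = ti, y = y, config = config,
                 alpha0 = config$alpha_0_treat, seed = NA_integer_,
                 replicate_id = d1$replicate[1]),
            class = "panel_data")
}

#' Write a matched cohort to CSV
#'
#' @param cohort a `matched_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- as.data.frame(cohort)
  d$method <- attr(cohort, "method")
  d$replicate <- attr(cohort, "replicate_id")
  utils::write.csv(d[c("replicate", "method", "interval", "treated_id",
                       "control_id", "weight")], path, row.names = FALSE)
  invisible(path)
}

term_to_list <- function(tm)
  list(vars = as.list(tm$vars), powers = as.list(tm$powers), coef = tm$coef)

term_from_list <- function(tl)
  model_term(tl$coef, unlist(tl$vars), unlist(tl$powers))

#' Write a scenario configuration to YAML
#'
#' @param config a `scenario_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
scenario_to_yaml <- function(config, path) {
  covs <- lapply(config$covariates, function(s)
    list(name = s$name, dist = s$dist, par = as.list(s$par),
         time_dependent = s$time_dependent, process = s$process,
         in_treatment = s$in_treatment, in_outcome = s$in_outcome))
  obj <- list(scenario_id = config$scenario_id,
              n_subjects = config$n_subjects,
              n_intervals = config$n_intervals,
              n_replicates = config$n_replicates,
              master_seed = config$master_seed,
              pairwise_rho = config$pairwise_rho,
              ar_phi = config$ar_phi, ma_theta = config$ma_theta,
              noise_sigma = config$noise_sigma,
              theta_true = config$theta_true,
              alpha_0_treat = config$alpha_0_treat,
              coefficients = config$coefficients,
              covariates = covs,
              treatment_model = lapply(config$treatment_model, term_to_list),
              outcome_model = lapply(config$outcome_model, term_to_list))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file written by [scenario_to_yaml()] (or hand-written
#'   with the same keys).
#' @return A `scenario_config`.
#' @export
scenario_from_yaml <- function(path) {
  o <- yaml::read_yaml(path)
  covs <- lapply(o$covariates, function(s)
    covariate_spec(s$name, s$dist, unlist(s$par),
                   time_dependent = s$time_dependent, process = s$process,
                   in_treatment = s$in_treatment, in_outcome = s$in_outcome))
  scenario_config(
    scenario_id = o$scenario_id, covariates = covs,
    pairwise_rho = o$pairwise_rho,
    treatment_model = lapply(o$treatment_model, term_from_list),
    outcome_model = lapply(o$outcome_model, term_from_list),
    coefficients = coefficient_set(o$coefficients$L, o$coefficients$M,
                                   o$coefficients$H),
    theta_true = o$theta_true,
    alpha_0_treat = o$alpha_0_treat %||% NA_real_,
    n_subjects = o$n_subjects, n_intervals = o$n_intervals,
    n_replicates = o$n_replicates, ar_phi = o$ar_phi,
    ma_theta = o$ma_theta, noise_sigma = o$noise_sigma,
    master_seed = o$master_seed)
}
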