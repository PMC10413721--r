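# shared fixtures: cached calibrated intercepts and hand-built panels

.cache <- new.env(parent = emptyenv())

cached_alpha0 <- function(scenario_id, target_rate = 1/3) {
  key <- paste0(scenario_id, "@", target_rate)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- calibrate_intercept(scenario_registry(scenario_id),
                                         target_rate = target_rate, seed = 11L)
  .cache[[key]]
}

# a scenario config whose treatment model is intercept-only (randomized
# treatment), optionally with zero outcome noise
randomized_config <- function(n = 300, T = 6, noise_sigma = 0) {
  scenario_config(scenario_id = "randomized",
                  treatment_model = list(),
                  alpha_0_treat = stats::qlogis(0.08),
                  n_subjects = n, n_intervals = T,
                  noise_sigma = noise_sigma)
}

# build a panel_data object from explicit pieces (crafted fixtures)
make_panel <- function(X, treat_interval, y = NULL,
                       config = scenario_config(
                         n_subjects = dim(X)[1], n_intervals = dim(X)[3],
                         alpha_0_treat = 0)) {
  if (is.null(y)) y <- matrix(0, dim(X)[1], dim(X)[3])
  structure(list(X = X, treat_interval = treat_interval, y = y,
                 config = config, alpha0 = config$alpha_0_treat,
                 seed = NA_integer_, replicate_id = 1L),
            class = "panel_data")
}

# covariate array of zeros with standard names, for hand-set values
zero_X <- function(n, T, K = 12) {
  array(0, c(n, K, T), dimnames = list(NULL, paste0("x", seq_len(K)), NULL))
}

# exhaustive-search 1:1 nearest neighbour with ties: the oracle the fast
# matcher is checked against
brute_nn <- function(treated_scores, control_scores, tol = 1e-12) {
  out <- NULL
  for (i in seq_along(treated_scores)) {
    d <- abs(treated_scores[i] - control_scores)
    sel <- which(d <= min(d) + tol)
    out <- rbind(out, data.frame(t = i, c = sel, weight = 1 / length(sel)))
  }
  out
}
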