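## Experiment orchestration: scenario x replicate loops with deterministic
## per-replicate seeding, optional balance reporting, and CSV output.

#' Define an experiment plan
#'
#' @param scenarios character vector of registry ids.
#' @param methods subset of `c("baseline_ps", "td_ps", "genmatch")`.
#' @param n_replicates Monte Carlo replicates per scenario.
#' @param master_seed experiment seed; replicate r of scenario s is a pure
#'   function of `(master_seed, s, r)`.
#' @param n_subjects optional override of each scenario's sample size.
#' @param target_rate ever-treated fraction the intercept is calibrated to.
#' @param ga [ga_config()] used when "genmatch" is requested.
#' @param balance also compute aggregate balance per replicate?
#' @param balance_n_boot KS bootstrap resamples for balance reporting.
#' @param out_dir optional directory for CSV output.
#' @param max_fail_frac abort if more than this fraction of replicates fail.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(scenarios = "base",
                            methods = c("baseline_ps", "td_ps"),
                            n_replicates = 200, master_seed = 1L,
                            n_subjects = NULL, target_rate = 1/3,
                            ga = ga_config(), balance = FALSE,
                            balance_n_boot = 1000,
                            out_dir = NULL, max_fail_frac = 0.05) {
  methods <- match.arg(methods, c("baseline_ps", "td_ps", "genmatch"),
                       several.ok = TRUE)
  stopifnot(length(methods) >= 1, n_replicates >= 1)
  if (!is.list(scenarios)) scenarios <- as.list(scenarios)
  for (s in scenarios)  # validate ids early; full configs pass through
    if (!inherits(s, "scenario_config")) scenario_registry(s)
  structure(list(scenarios = scenarios, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 n_subjects = n_subjects, target_rate = target_rate,
                 ga = ga, balance = balance,
                 balance_n_boot = balance_n_boot,
                 out_dir = out_dir, max_fail_frac = max_fail_frac),
            class = "experiment_plan")
}

## seed offset per scenario so scenario streams do not collide
scenario_seed <- function(master_seed, scenario_id) {
  replicate_seed(master_seed, 1L + sum(utf8ToInt(scenario_id)))
}

## one replicate: simulate, fit, match, estimate (and optionally balance)
run_replicate <- function(cfg, alpha0, r, seed, plan) {
  panel <- simulate_panel(cfg, seed = seed, alpha0 = alpha0,
                          replicate_id = r)
  needs_td <- any(plan$methods %in% c("td_ps", "genmatch"))
  bl <- if ("baseline_ps" %in% plan$methods) fit_baseline_ps(panel)
  td <- if (needs_td) fit_td_cox(panel)
  cohorts <- list()
  if ("baseline_ps" %in% plan$methods)
    cohorts$baseline_ps <- match_baseline_ps(bl, panel)
  if ("td_ps" %in% plan$methods)
    cohorts$td_ps <- match_td_ps(td, panel)
  if ("genmatch" %in% plan$methods) {
    ga <- plan$ga; ga$seed <- replicate_seed(ga$seed, seed %% 100000L)
    cohorts$genmatch <- match_genetic(panel, td, ga)
  }
  est <- lapply(cohorts, estimate_effect, panel = panel)
  bal <- if (plan$balance) {
    do.call(rbind, lapply(names(cohorts), function(m) {
      b <- aggregate_balance(cohorts[[m]], panel,
                             n_boot = plan$balance_n_boot,
                             seed = replicate_seed(seed, 999L))
      b$method <- m; b$replicate <- r
      b
    }))
  }
  list(estimates = est, balance = bal)
}

#' Run a full matching experiment
#'
#' For every scenario: calibrates the treatment-model intercept, then for
#' every replicate generates a panel, fits the requested propensity models,
#' runs each matcher and estimates the treatment effect (optionally with an
#' aggregate balance report). Replicates are seeded independently, so
#' results do not depend on execution order; isolated replicate failures
#' are collected and only abort the run beyond `max_fail_frac`.
#'
#' @param plan an [experiment_plan()].
#' @return List with `estimates` (data frame), `summary` (per scenario and
#'   method), `balance` (data frame or NULL), `intercepts`, and `failures`.
#' @export
run_experiment <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  all_est <- list(); all_bal <- list(); all_sum <- list()
  intercepts <- numeric(); failures <- list()
  for (sc in plan$scenarios) {
    cfg <- if (inherits(sc, "scenario_config")) sc else scenario_registry(sc)
    sid <- cfg$scenario_id
    if (!is.null(plan$n_subjects)) cfg$n_subjects <- plan$n_subjects
    sseed <- scenario_seed(plan$master_seed, sid)
    alpha0 <- if (!is.na(cfg$alpha_0_treat)) cfg$alpha_0_treat
    else calibrate_intercept(cfg, target_rate = plan$target_rate,
                             seed = sseed)
    intercepts[sid] <- alpha0
    res <- vector("list", plan$n_replicates)
    nfail <- 0
    for (r in seq_len(plan$n_replicates)) {
      seed_r <- replicate_seed(sseed, r)
      res[[r]] <- tryCatch(
        run_replicate(cfg, alpha0, r, seed_r, plan),
        error = function(e) {
          failures[[length(failures) + 1]] <<-
            list(scenario = sid, replicate = r, message = conditionMessage(e))
          NULL
        })
      if (is.null(res[[r]])) nfail <- nfail + 1
    }
    if (nfail > plan$max_fail_frac * plan$n_replicates)
      stop(nfail, " of ", plan$n_replicates, " replicates failed in scenario ",
           sid, "; first error: ", failures[[1]]$message)
    res <- res[!vapply(res, is.null, TRUE)]
    est <- do.call(rbind, lapply(res, function(x)
      do.call(rbind, lapply(x$estimates, function(e)
        data.frame(scenario = sid, method = e$method,
                   replicate = e$replicate_id, theta_hat = e$theta_hat,
                   var_hat = e$var_hat, se_hat = e$se_hat,
                   n_treated = e$n_treated, n_unmatched = e$n_unmatched)))))
    rownames(est) <- NULL
    all_est[[sid]] <- est
    sm <- summarize_estimates(est, theta_true = cfg$theta_true)
    sm <- cbind(scenario = sid, sm)
    all_sum[[sid]] <- sm
    if (plan$balance)
      all_bal[[sid]] <- cbind(scenario = sid,
                              do.call(rbind, lapply(res, `[[`, "balance")))
  }
  out <- list(estimates = do.call(rbind, c(all_est, list(make.row.names = FALSE))),
              summary = do.call(rbind, c(all_sum, list(make.row.names = FALSE))),
              balance = if (plan$balance)
                do.call(rbind, c(all_bal, list(make.row.names = FALSE))),
              intercepts = intercepts, failures = failures)
  if (!is.null(plan$out_dir)) {
    dir.create(plan$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$estimates,
                     file.path(plan$out_dir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(out$summary, file.path(plan$out_dir, "summary.csv"),
                     row.names = FALSE)
    if (!is.null(out$balance))
      utils::write.csv(out$balance, file.path(plan$out_dir, "balance.csv"),
                       row.names = FALSE)
  }
  out
}
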