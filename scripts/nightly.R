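#!/usr/bin/env Rscript
# Long-running verification sweeps that do not fit the per-commit suite:
#   (a) genetic-matching bias in scenarios A and C at M = 50 replicates of
#       n = 1,000 with the reduced search budget (population 25, 15
#       generations) — takes hours on one CPU;
#   (b) baseline-PS bias in every scenario at M = 200.
#
# Usage: Rscript scripts/nightly.R [--seed <int>] [--out <path>]

suppressPackageStartupMessages({
  library(longmatch)
  library(optparse)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/nightly.json"))))

seed <- opt$seed
dir.create(dirname(opt$out), recursive = TRUE, showWarnings = FALSE)
pct_bias <- function(th) 100 * abs(mean(1 - th))
out <- list()

## (a) genetic matching, scenarios A and C
for (sid in c("A", "C")) {
  cfg <- scenario_registry(sid)
  a0 <- calibrate_intercept(cfg, seed = replicate_seed(seed, 7L))
  th <- numeric(50)
  for (r in seq_len(50)) {
    p <- simulate_panel(cfg, replicate_seed(replicate_seed(seed, 50L), r),
                        alpha0 = a0, replicate_id = r)
    td <- fit_td_cox(p)
    ga <- ga_config(population_size = 25, max_generations = 15,
                    n_bootstrap = 250, seed = replicate_seed(seed, 900L + r))
    th[r] <- estimate_effect(match_genetic(p, td, ga), p)$theta_hat
    message(sprintf("genmatch %s replicate %d: theta = %.3f", sid, r, th[r]))
  }
  out[[paste0("genmatch_bias_", sid)]] <- list(value = pct_bias(th), n = 50L)
}

## (b) baseline-PS bias in every scenario
for (sid in c("base", LETTERS[1:6])) {
  cfg <- scenario_registry(sid)
  a0 <- calibrate_intercept(cfg, seed = replicate_seed(seed, 7L))
  th <- vapply(seq_len(200), function(r) {
    p <- simulate_panel(cfg, replicate_seed(replicate_seed(seed, 60L), r),
                        alpha0 = a0, replicate_id = r)
    estimate_effect(match_baseline_ps(fit_baseline_ps(p), p), p)$theta_hat
  }, numeric(1))
  out[[paste0("baseline_bias_", sid)]] <- list(value = pct_bias(th), n = 200L)
  message(sprintf("baseline %s: pct bias = %.1f", sid,
                  out[[paste0("baseline_bias_", sid)]]$value))
}

jsonlite::write_json(out, opt$out, auto_unbox = TRUE, digits = NA)
message("wrote ", opt$out)
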