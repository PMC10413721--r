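test_that("risk sets follow the not-yet-treated definition", {
  X <- zero_X(3, 3)
  pan <- make_panel(X, c(1L, 2L, NA),
                    config = scenario_config(n_subjects = 3, n_intervals = 3,
                                             alpha_0_treat = 0))
  rs <- build_risk_sets(pan)
  expect_length(rs, 2)
  expect_equal(rs[[1]]$interval, 1)
  expect_equal(rs[[1]]$treated, 1)
  expect_equal(rs[[1]]$controls, c(2, 3))
  expect_equal(rs[[2]]$treated, 2)
  expect_equal(rs[[2]]$controls, 3)
  # a treated subject never reappears as control at its interval or later
  for (r in rs) expect_length(intersect(r$treated, r$controls), 0)
  expect_warning(build_risk_sets(make_panel(X, rep(NA_integer_, 3))),
                 "no treated")
})

test_that("nearest-neighbour matching agrees with the exhaustive oracle", {
  # printed examples
  m <- longmatch:::nn_with_ties(0.40, c(0.10, 0.39, 0.70))
  expect_equal(m$c, 2); expect_equal(m$weight, 1)
  m2 <- longmatch:::nn_with_ties(0.50, c(0.45, 0.55))
  expect_equal(sort(m2$c), c(1, 2))
  expect_equal(m2$weight, c(0.5, 0.5))
  # randomized property: 300 instances of <= 20 subjects, incl. exact ties
  set.seed(99)
  for (i in 1:300) {
    nt <- sample(1:6, 1); nc <- sample(1:14, 1)
    pool <- round(rnorm(8), 2)  # coarse values force frequent ties
    ts <- sample(pool, nt, replace = TRUE)
    cs <- sample(pool, nc, replace = TRUE)
    got <- longmatch:::nn_with_ties(ts, cs)
    want <- brute_nn(ts, cs)
    expect_equal(got[order(got$t, got$c), ], want[order(want$t, want$c), ],
                 ignore_attr = TRUE)
  }
})

test_that("weight is conserved: each treated subject carries total control weight 1", {
  cfg <- scenario_registry("base")
  p <- simulate_panel(cfg, seed = 55, alpha0 = -4.7)
  cb <- match_baseline_ps(fit_baseline_ps(p), p)
  ct <- match_td_ps(fit_td_cox(p), p)
  for (co in list(cb, ct)) {
    tot <- tapply(co$weight, co$treated_id, sum)
    expect_equal(as.numeric(tot), rep(1, length(tot)))
    expect_setequal(as.integer(names(tot)),
                    setdiff(which(!is.na(p$treat_interval)),
                            attr(co, "unmatched")))
  }
})

test_that("sequential matching respects risk sets and later eligibility", {
  # subject 2 is the closest control at t = 1, then treated at t = 2
  X <- zero_X(3, 2)
  X[, "x1", 1] <- c(1.0, 0.9, 0.2)
  X[, "x1", 2] <- c(1.0, 0.9, 0.2)
  pan <- make_panel(X, c(1L, 2L, NA),
                    config = scenario_config(n_subjects = 3, n_intervals = 2,
                                             alpha_0_treat = 0))
  fake <- list(coefficients = c(x1 = 1, setNames(rep(0, 9), paste0("x", 2:10))))
  co <- match_td_ps(fake, pan)
  expect_equal(co$control_id[co$interval == 1], 2)
  expect_equal(co$treated_id[co$interval == 2], 2)
  expect_equal(co$control_id[co$interval == 2], 3)
})

test_that("risk-set sizes are monotone and matched controls were eligible", {
  p <- simulate_panel(scenario_registry("base"), seed = 56, alpha0 = -4.7)
  rs <- build_risk_sets(p)
  sizes <- vapply(rs, function(r) length(r$controls), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  co <- match_td_ps(fit_td_cox(p), p)
  ti <- p$treat_interval
  expect_true(all(is.na(ti[co$control_id]) |
                    ti[co$control_id] > co$interval))
})

test_that("matching is unbiased under randomized treatment", {
  cfg <- randomized_config(n = 250, T = 4, noise_sigma = 0)
  th <- vapply(1:200, function(r) {
    p <- simulate_panel(cfg, seed = replicate_seed(7, r), replicate_id = r)
    estimate_effect(match_baseline_ps(fit_baseline_ps(p), p), p)$theta_hat
  }, numeric(1))
  expect_lt(abs(mean(th) - 1), 3 * sd(th) / sqrt(length(th)))
})

test_that("a risk set without controls leaves its treated subjects unmatched", {
  X <- zero_X(3, 2)
  X[, "x1", ] <- c(0.3, 0.2, 0.9)
  pan <- make_panel(X, c(1L, 2L, 2L),
                    config = scenario_config(n_subjects = 3, n_intervals = 2,
                                             alpha_0_treat = 0))
  fake <- list(coefficients = c(x1 = 1, setNames(rep(0, 9), paste0("x", 2:10))))
  expect_warning(co <- match_td_ps(fake, pan), "no controls")
  expect_setequal(attr(co, "unmatched"), c(2, 3))
  expect_equal(co$treated_id, 1)  # interval-1 match still made
})

test_that("baseline matching requires never-treated controls", {
  p <- simulate_panel(scenario_registry("base"), seed = 57, alpha0 = -4.7)
  fit <- fit_baseline_ps(p)
  p2 <- p
  p2$treat_interval[is.na(p2$treat_interval)] <- 6L
  expect_error(match_baseline_ps(fit, p2), "never-treated")
})
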