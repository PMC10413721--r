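test_that("covariate marginals are recovered at interval 1", {
  cfg <- scenario_registry("base")
  X <- draw_covariate_paths(cfg, n = 50000, seed = 101)
  se_b <- sqrt(0.25 / 50000)           # binary mean
  se_m <- 1 / sqrt(50000)              # normal mean
  expect_lt(abs(mean(X[, "x1", 1]) - 0.5), 4 * se_b)
  expect_lt(abs(mean(X[, "x6", 1])), 4 * se_m)
  expect_lt(abs(var(X[, "x6", 1]) - 1), 4 * sqrt(2 / 50000))
  # scenario E and F marginals
  XE <- draw_covariate_paths(scenario_registry("E"), n = 50000, seed = 102)
  expect_lt(abs(mean(XE[, "x9", 1]) - 2), 4 * se_m)
  XF <- draw_covariate_paths(scenario_registry("F"), n = 50000, seed = 103)
  expect_lt(abs(mean(XF[, "x9", 1]) - 2), 4 * sqrt(2 / 50000))   # Poisson(2)
  expect_lt(abs(mean(XF[, "x10", 1]) - 2), 4 * sqrt(2 / 50000))  # Gamma(2,1)
  expect_true(all(XF[, "x9", ] >= 0 & XF[, "x9", ] == round(XF[, "x9", ])))
})

test_that("time-invariant covariates are constant across intervals", {
  cfg <- scenario_registry("base")
  X <- draw_covariate_paths(cfg, n = 200, seed = 7)
  for (v in c("x1", "x2", "x3", "x6", "x7", "x8"))
    expect_true(all(X[, v, ] == X[, v, 1]))
  for (v in c("x4", "x5", "x9", "x10"))
    expect_false(all(X[, v, 2] == X[, v, 1]))
})

test_that("independence and exchangeable correlation follow the config", {
  X <- draw_covariate_paths(scenario_registry("base"), n = 50000, seed = 5)
  expect_lt(abs(cor(X[, "x6", 1], X[, "x7", 1])), 4 / sqrt(50000))
  # rho = 0.7 on the latent scale: continuous pairs realize rho directly
  XC <- draw_covariate_paths(scenario_registry("C"), n = 50000, seed = 6)
  expect_lt(abs(cor(XC[, "x6", 1], XC[, "x7", 1]) - 0.7), 0.02)
  expect_gt(cor(XC[, "x1", 1], XC[, "x2", 1]), 0.3)  # attenuated for binaries
})

test_that("AR(1) and MA(1) autocorrelations match closed forms", {
  n <- 50000
  se <- 4 / sqrt(n)
  X <- draw_covariate_paths(scenario_registry("base"), n = n, seed = 21)
  phi <- scenario_registry("base")$ar_phi
  expect_lt(abs(cor(X[, "x9", 1], X[, "x9", 2]) - phi), se)
  expect_lt(abs(cor(X[, "x9", 1], X[, "x9", 3]) - phi^2), se)
  XD <- draw_covariate_paths(scenario_registry("D"), n = n, seed = 22)
  th <- scenario_registry("D")$ma_theta
  expect_lt(abs(cor(XD[, "x9", 1], XD[, "x9", 2]) - th / (1 + th^2)), se)
  expect_lt(abs(cor(XD[, "x9", 1], XD[, "x9", 3])), se)  # MA(1) lag-2 is 0
  # stationary unit variance at every interval
  expect_lt(max(abs(apply(X[, "x9", ], 2, var) - 1)), 4 * sqrt(2 / n))
})

test_that("configuration errors are caught", {
  expect_error(scenario_config(pairwise_rho = 1), "pairwise_rho")
  expect_error(scenario_config(pairwise_rho = -0.1), "pairwise_rho")
  expect_error(covariate_spec("x1", "weibull", c(1, 1)), "arg")
  expect_error(covariate_spec("x1", "normal", c(mu = 0, sd = 1),
                              time_dependent = FALSE, process = "ar1"),
               "process")
  expect_error(scenario_registry("Z"), "valid ids")
  # outcome model naming an unknown covariate
  cfg <- scenario_config(outcome_model = list(longmatch:::model_term("L", "x99")),
                         alpha_0_treat = 0)
  expect_error(simulate_panel(cfg, seed = 1), "unknown covariate")
})

test_that("treatment assignment matches closed-form probabilities", {
  # intercept 0, only x3 (high effect): P(treat | x3 = 1) = plogis(log 1.75)
  cfg <- scenario_config(
    treatment_model = list(longmatch:::model_term("H", "x3")),
    alpha_0_treat = 0, n_subjects = 20000, n_intervals = 1)
  X <- draw_covariate_paths(cfg, seed = 31)
  ti <- assign_treatment(X, cfg, seed = 32)
  p1 <- mean(!is.na(ti[X[, "x3", 1] == 1]))
  p0 <- mean(!is.na(ti[X[, "x3", 1] == 0]))
  expect_lt(abs(p1 - plogis(log(1.75))), 4 * sqrt(0.25 / 10000))
  expect_lt(abs(p0 - 0.5), 4 * sqrt(0.25 / 10000))
  # effectively -infinite intercept: nobody treated
  ti0 <- assign_treatment(X, cfg, seed = 33, alpha0 = -1e6)
  expect_true(all(is.na(ti0)))
})

test_that("no anticipation: future covariates cannot affect assignment", {
  cfg <- scenario_registry("base")
  X <- draw_covariate_paths(cfg, n = 400, seed = 41)
  ti <- assign_treatment(X, cfg, seed = 42, alpha0 = -4.7)
  X2 <- X
  X2[, , 5:6] <- X2[sample(400), , 5:6]  # permute intervals 5 and 6
  ti2 <- assign_treatment(X2, cfg, seed = 42, alpha0 = -4.7)
  up_to_4 <- !is.na(ti) & ti <= 4
  expect_identical(ti[up_to_4], ti2[up_to_4])
  expect_identical(which(up_to_4),
                   which(!is.na(ti2) & ti2 <= 4))
})

test_that("outcome model reproduces hand-computed values", {
  cfg <- scenario_config(alpha_0_treat = 0, noise_sigma = 0,
                         n_subjects = 3, n_intervals = 2)
  X <- zero_X(3, 2)
  X[2, "x1", ] <- 1; X[2, "x5", ] <- 1
  X[3, "x1", ] <- 1; X[3, "x5", ] <- 1
  ti <- c(1L, NA, 1L)
  y <- generate_outcome(X, ti, cfg, seed = 1)
  expect_equal(y[1, 1], 1)                                  # effect only
  expect_equal(y[2, 2], log(1.25) + log(1.75))              # 0.7828
  expect_equal(y[3, 1], 1 + log(1.25) + log(1.75))
  # treated-at-1 subject keeps z = 1 at interval 2
  expect_equal(y[1, 2], 1)
})

test_that("panels are deterministic in (config, seed) and treated at most once", {
  cfg <- scenario_registry("base")
  p1 <- simulate_panel(cfg, seed = 99, alpha0 = -4.7)
  p2 <- simulate_panel(cfg, seed = 99, alpha0 = -4.7)
  expect_identical(p1$X, p2$X)
  expect_identical(p1$treat_interval, p2$treat_interval)
  expect_identical(p1$y, p2$y)
  p3 <- simulate_panel(cfg, seed = 100, alpha0 = -4.7)
  expect_false(identical(p1$treat_interval, p3$treat_interval))
  expect_true(all(is.na(p1$treat_interval) |
                    (p1$treat_interval >= 1 & p1$treat_interval <= 6)))
  reps <- generate_replicates(cfg, n_replicates = 2, master_seed = 3,
                              alpha0 = -4.7)
  reps2 <- generate_replicates(cfg, n_replicates = 2, master_seed = 3,
                               alpha0 = -4.7)
  expect_identical(reps[[1]]$y, reps2[[1]]$y)
  expect_false(identical(reps[[1]]$treat_interval, reps[[2]]$treat_interval))
})

test_that("intercept calibration solves the closed-form case and flags bad targets", {
  # intercept-only model: ever-treated rate over T=1 is plogis(a0)
  cfg <- scenario_config(treatment_model = list(), n_subjects = 1000,
                         n_intervals = 1)
  a0 <- calibrate_intercept(cfg, target_rate = 0.25, seed = 3)
  expect_lt(abs(a0 - qlogis(0.25)), 0.1)
  expect_error(calibrate_intercept(cfg, target_rate = 1e-9, seed = 3),
               "degenerate")
  # unreachable target: rate cannot exceed ~plogis(10) pilot noise under
  # an intercept-only model, let alone 0.999 with tol tightened
  expect_error(calibrate_intercept(cfg, target_rate = 0.9999, tol = 1e-5,
                                   pilot_reps = 2, seed = 3),
               "unreachable|converge")
})
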