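test_that("generalized Mahalanobis distance reduces to known cases", {
  # identity covariance, unit weights: Euclidean
  expect_equal(gen_mahalanobis(c(3, 4), c(0, 0), diag(2)), 5)
  expect_equal(gen_mahalanobis(c(1, 2), c(1, 2), diag(2)), 0)
  # W = I equals classical Mahalanobis on random PD matrices
  set.seed(4)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 0.1
    d <- rnorm(k)
    expect_equal(gen_mahalanobis(d, rep(0, k), S),
                 sqrt(drop(t(d) %*% solve(S) %*% d)), tolerance = 1e-10)
    # symmetry
    x <- rnorm(k); y <- rnorm(k); w <- runif(k)
    expect_equal(gen_mahalanobis(x, y, S, w), gen_mahalanobis(y, x, S, w))
  }
})

test_that("weighted distance matches a dense inverse-square-root oracle", {
  S <- matrix(c(2, 1, 1, 2), 2)
  w <- c(1, 4)
  d <- c(1, 1)
  L <- t(chol(S))          # S = L L'
  A <- solve(L)            # explicit dense inverse square root
  want <- sqrt(drop(t(d) %*% t(A) %*% diag(w) %*% A %*% d))
  expect_equal(gen_mahalanobis(d, c(0, 0), S, w), want, tolerance = 1e-10)
})

test_that("lexical comparison maximizes the minimum p-value first", {
  expect_equal(lexical_compare(c(0.30, 0.9), c(0.20, 0.99)), 1L)
  expect_equal(lexical_compare(c(0.2, 0.5), c(0.2, 0.4)), 1L)
  expect_equal(lexical_compare(c(0.2, 0.4), c(0.4, 0.2)), 0L)  # same sorted
  expect_equal(lexical_compare(c(0.1, 0.9), c(0.2, 0.3)), -1L)
})

# small deterministic risk-set problem used across GA tests
toy_problem <- function(seed = 2, n_t = 12, n_c = 60, loss = "lexical-pv") {
  set.seed(seed)
  Mm <- cbind(x1 = c(rbinom(n_t, 1, 0.7), rbinom(n_c, 1, 0.4)),
              x6 = c(rnorm(n_t, 0.8), rnorm(n_c)))
  ga <- ga_config(population_size = 8, max_generations = 5,
                  n_bootstrap = 100, seed = 5, loss = loss)
  longmatch:::risk_set_problem(Mm, n_t, Mm, c(x1 = TRUE, x6 = FALSE), ga, 1L)
}

test_that("candidate loss is deterministic and scale invariant", {
  prob <- toy_problem()
  l1 <- evaluate_candidate(c(1, 3), prob)
  l2 <- evaluate_candidate(c(1, 3), prob)
  expect_identical(l1, l2)
  l3 <- evaluate_candidate(c(10, 30), prob)  # same relative weights
  expect_identical(l1, l3)
  expect_true(all(l1 >= 0 & l1 <= 1))
  expect_equal(l1, sort(l1))
})

test_that("identical treated and control sets give perfect balance", {
  set.seed(3)
  Mm <- cbind(x1 = rep(rbinom(10, 1, 0.5), 2), x6 = rep(rnorm(10), 2))
  ga <- ga_config(population_size = 8, max_generations = 2,
                  n_bootstrap = 100, seed = 5)
  prob <- longmatch:::risk_set_problem(Mm, 10, Mm,
                                       c(x1 = TRUE, x6 = FALSE), ga, 1L)
  expect_equal(evaluate_candidate(c(1, 1), prob), rep(1, 3))
})

test_that("the genetic search is elitist and beats a coarse grid", {
  prob <- toy_problem()
  ga <- ga_config(population_size = 10, max_generations = 6,
                  wait_generations = 6, n_bootstrap = 100, seed = 21)
  res <- evolve_weights(prob, ga)
  # best-so-far loss is lexically non-decreasing generation over generation
  for (g in seq_along(res$trace)[-1])
    expect_gte(lexical_compare(res$trace[[g]], res$trace[[g - 1]]), 0)
  # at least as good as a coarse grid over the relative weight
  grid <- lapply(c(0.01, 0.1, 0.5, 1, 2, 10, 100), function(r)
    evaluate_candidate(c(r, 1), prob))
  best_grid <- grid[[longmatch:::lexical_order(grid)[1]]]
  expect_gte(lexical_compare(res$loss, best_grid), 0)
  # deterministic given the seed
  res2 <- evolve_weights(prob, ga)
  expect_identical(res$weights, res2$weights)
  expect_identical(res$loss, res2$loss)
})

test_that("mean standardized-difference loss is available", {
  prob <- toy_problem(loss = "mean-stddiff")
  l <- evaluate_candidate(c(1, 1), prob)
  expect_length(l, 1)
  expect_lte(l, 0)  # negated mean standardized difference
})

test_that("zero generations reduces to unweighted Mahalanobis risk-set matching", {
  p <- simulate_panel(scenario_registry("base"), seed = 77, alpha0 = -4.7)
  td <- fit_td_cox(p)
  co <- match_genetic(p, td, ga_config(max_generations = 0))
  # reproduce one risk set by hand with W = I
  rs <- build_risk_sets(p)[[2]]
  lp <- td_linear_predictor(td, p)
  members <- c(rs$treated, rs$controls)
  Mm <- cbind(p$X[members, paste0("x", 1:10), rs$interval],
              .ps = exp(lp[members, rs$interval] - max(lp[, rs$interval])))
  Y <- longmatch:::whiten(Mm, cov(Mm))
  nt <- length(rs$treated)
  m <- longmatch:::weighted_nn_match(Y[1:nt, ], Y[-(1:nt), ], rep(1, 11))
  got <- co[co$interval == rs$interval, ]
  expect_setequal(paste(got$treated_id, got$control_id),
                  paste(rs$treated[m$t], rs$controls[m$c]))
})

test_that("the propensity-score column can enter the loss or be omitted", {
  p <- simulate_panel(scenario_registry("base", n_subjects = 120), seed = 79,
                      alpha0 = -4.7)
  td <- fit_td_cox(p)
  for (mode in c("distance+loss", "none")) {
    ga <- ga_config(population_size = 4, max_generations = 1,
                    n_bootstrap = 100, seed = 2, include_ps = mode)
    co <- match_genetic(p, if (mode == "none") NULL else td, ga)
    expect_s3_class(co, "matched_cohort")
    expect_gt(nrow(co), 0)
  }
})

test_that("full longitudinal genetic matching is reproducible and weight-conserving", {
  p <- simulate_panel(scenario_registry("base", n_subjects = 150), seed = 78,
                      alpha0 = -4.7)
  td <- fit_td_cox(p)
  ga <- ga_config(population_size = 6, max_generations = 2,
                  n_bootstrap = 100, seed = 9)
  c1 <- match_genetic(p, td, ga)
  c2 <- match_genetic(p, td, ga)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  tot <- tapply(c1$weight, c1$treated_id, sum)
  expect_equal(as.numeric(tot), rep(1, length(tot)))
  tr <- attr(c1, "trace")
  expect_true(all(vapply(tr, function(x) x$generations <= 2, TRUE)))
})
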