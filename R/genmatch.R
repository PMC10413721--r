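## Longitudinal genetic matching: per risk set, an evolutionary search over
## the diagonal weight matrix of a generalized Mahalanobis distance,
## maximizing lexically-ordered covariate-balance p-values, followed by 1:1
## nearest-neighbour matching under the optimized distance.

## lower-triangular Cholesky factor L with S = L L', ridge-regularized when
## near-singular (small risk sets late in follow-up can degenerate)
chol_lower <- function(S, ridge = 1e-8) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch) && ridge > 0) {
    S <- S + diag(ridge * sum(diag(S)) / ncol(S), ncol(S))
    ch <- tryCatch(chol(S), error = function(e) NULL)
  }
  if (is.null(ch)) {
    v <- diag(S)
    stop("covariance of matching variables is singular after regularization; ",
         "near-constant variables: ",
         paste(colnames(S)[v <= 1e-12 * max(v)], collapse = ", "))
  }
  t(ch)
}

#' Generalized (weighted) Mahalanobis distance
#'
#' `sqrt((x_i - x_j)' (S^{-1/2})' W (S^{-1/2}) (x_i - x_j))` where
#' `S^{-1/2}` is the inverse of the lower Cholesky factor of the sample
#' covariance S and W is a non-negative diagonal weight matrix. With
#' `w = 1` for every variable this is the classical Mahalanobis distance.
#'
#' @param x_i,x_j covariate vectors.
#' @param S positive-definite sample covariance of the matching variables.
#' @param w diagonal weights (non-negative), default all 1.
#' @return Non-negative distance.
#' @export
gen_mahalanobis <- function(x_i, x_j, S, w = rep(1, ncol(S))) {
  stopifnot(length(x_i) == length(x_j), length(w) == ncol(S), all(w >= 0))
  u <- forwardsolve(chol_lower(S), x_i - x_j)
  sqrt(sum(w * u^2))
}

## rows of M mapped to the whitened coordinate system: Y = (L^{-1} M')'
## so that the weighted distance is a diagonal quadratic form in Y
whiten <- function(M, S) t(forwardsolve(chol_lower(S), t(M)))

## 1:1 NN matching in whitened coordinates under diagonal weights w,
## with replacement and ties
weighted_nn_match <- function(Yt, Yc, w, tol = 1e-12) {
  A <- sweep(Yt, 2, sqrt(w), `*`)
  B <- sweep(Yc, 2, sqrt(w), `*`)
  D <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) -
                   2 * tcrossprod(A, B), 0))
  dmin <- apply(D, 1, min)
  sel <- D <= dmin + tol
  idx <- which(sel, arr.ind = TRUE)
  k <- rowSums(sel)
  data.frame(t = idx[, 1], c = idx[, 2], weight = 1 / k[idx[, 1]])
}

#' Compare two lexical loss vectors
#'
#' Candidate balance is summarized by the vector of its p-values sorted
#' ascending; `a` beats `b` if, at the first position where the sorted
#' vectors differ, `a` is larger (improve the worst-balanced variable
#' first, then the next worst, and so on).
#'
#' @param a,b numeric loss vectors of equal length.
#' @return `1L` if `a` wins, `-1L` if `b` wins, `0L` on exact equality.
#' @export
lexical_compare <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- sort(a); sb <- sort(b)
  d <- which(sa != sb)
  if (!length(d)) return(0L)
  if (sa[d[1]] > sb[d[1]]) 1L else -1L
}

## order candidate losses best-first
lexical_order <- function(losses) {
  Lm <- do.call(rbind, lapply(losses, sort))
  do.call(order, c(lapply(seq_len(ncol(Lm)), function(j) Lm[, j]),
                   list(decreasing = TRUE)))
}

#' Genetic-search configuration
#'
#' @param population_size candidates per generation (>= 2).
#' @param max_generations generation cap; 0 skips the search and keeps
#'   identity weights (plain Mahalanobis risk-set matching).
#' @param wait_generations stop after this many generations without
#'   lexical improvement of the best candidate.
#' @param weight_domain numeric `c(lo, hi)` domain for each diagonal weight.
#' @param n_bootstrap KS bootstrap resamples inside the loss (kept small;
#'   final balance reporting uses more).
#' @param seed integer seed; the whole search is deterministic given it.
#' @param loss "lexical-pv" (sorted KS/t p-values, the default) or
#'   "mean-stddiff" (minimize the mean standardized difference).
#' @param include_ps how the proxied time-dependent propensity score enters:
#'   "distance" (a matching variable only, the default), "distance+loss"
#'   (also assessed in the loss), or "none".
#' @param operator_mix named proportions for the generation operators.
#' @param tie_tol distance tie tolerance.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, max_generations = 30,
                      wait_generations = 4, weight_domain = c(0, 1000),
                      n_bootstrap = 250, seed = 1L,
                      loss = c("lexical-pv", "mean-stddiff"),
                      include_ps = c("distance", "distance+loss", "none"),
                      operator_mix = c(clone = 0.10, unif_mut = 0.20,
                                       bound_mut = 0.10, nonunif_mut = 0.20,
                                       arith_xover = 0.15, heur_xover = 0.15,
                                       resample = 0.10),
                      tie_tol = 1e-12) {
  stopifnot(population_size >= 2, weight_domain[1] >= 0,
            weight_domain[2] > weight_domain[1], n_bootstrap >= 100)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 wait_generations = as.integer(wait_generations),
                 weight_domain = weight_domain,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed),
                 loss = match.arg(loss), include_ps = match.arg(include_ps),
                 operator_mix = operator_mix / sum(operator_mix),
                 tie_tol = tie_tol),
            class = "ga_config")
}

## bundle everything a candidate evaluation needs for one risk set
risk_set_problem <- function(Mm, n_treated, balance_mat, binary, ga,
                             interval = NA_integer_) {
  iv <- if (is.na(interval)) 1L else interval
  S <- stats::cov(Mm)
  Y <- whiten(Mm, S)
  it <- seq_len(n_treated)
  list(Yt = Y[it, , drop = FALSE], Yc = Y[-it, , drop = FALSE],
       Bt = balance_mat[it, , drop = FALSE],
       Bc = balance_mat[-it, , drop = FALSE],
       binary = binary, n_boot = ga$n_bootstrap,
       seed = replicate_seed(ga$seed, iv),
       loss = ga$loss, tie_tol = ga$tie_tol, interval = iv, S = S)
}

#' Evaluate one candidate weight vector
#'
#' Matches under the weighted generalized Mahalanobis distance implied by
#' `w`, then computes per-variable balance p-values on the matched cohort:
#' binary variables contribute a weighted paired t-test p-value, continuous
#' variables both a bootstrapped KS and a paired t-test p-value. The
#' bootstrap sub-seed is fixed by the problem, so the loss is a
#' deterministic function of `w`.
#'
#' @param w non-negative diagonal weights.
#' @param problem a risk-set problem built inside [match_genetic()] (or by
#'   tests).
#' @return For the lexical loss, the p-values sorted ascending; for
#'   "mean-stddiff", the negated mean standardized difference (so that
#'   larger is always better).
#' @export
evaluate_candidate <- function(w, problem) {
  pairs <- weighted_nn_match(problem$Yt, problem$Yc, w, problem$tie_tol)
  B_t <- problem$Bt[pairs$t, , drop = FALSE]
  B_c <- problem$Bc[pairs$c, , drop = FALSE]
  wt <- pairs$weight
  if (problem$loss == "mean-stddiff") {
    sds <- vapply(seq_len(ncol(B_t)), function(k)
      standardized_difference(B_t[, k], B_c[, k], wt, wt), numeric(1))
    return(-mean(sds))
  }
  ps <- lapply(seq_len(ncol(B_t)), function(k) {
    pt_ <- paired_t_p(B_t[, k] - B_c[, k], wt)
    if (problem$binary[k]) pt_
    else c(bootstrap_ks_p(B_t[, k], B_c[, k], wt, wt,
                          n_boot = problem$n_boot,
                          seed = replicate_seed(problem$seed, k)),
           pt_)
  })
  sort(unlist(ps))
}

#' Evolve the diagonal weight matrix for one risk set
#'
#' Real-coded elitist genetic search: the population is initialized with
#' identity weights plus uniform draws over the weight domain; each
#' generation keeps the best-so-far candidate unchanged and fills the rest
#' via tournament-selected parents passed through mutation (uniform,
#' boundary, non-uniform shrinking), arithmetic and heuristic crossover,
#' cloning, and whole-vector resampling. Stops at `max_generations` or when
#' the best loss has not improved for `wait_generations`. Deterministic
#' given `ga$seed`; the best-so-far loss is lexically non-decreasing across
#' generations by construction.
#'
#' @param problem risk-set problem (see [evaluate_candidate()]).
#' @param ga a [ga_config()].
#' @return List with `weights`, `loss`, `generations` used, and `trace`
#'   (best loss per generation).
#' @export
evolve_weights <- function(problem, ga = ga_config()) {
  K <- ncol(problem$Yt)
  lo <- ga$weight_domain[1]; hi <- ga$weight_domain[2]
  P <- ga$population_size
  clamp <- function(x) pmin(pmax(x, lo), hi)
  with_seed(replicate_seed(ga$seed, problem$interval), {
    pop <- rbind(rep(1, K),
                 matrix(stats::runif((P - 1) * K, lo, hi), P - 1, K))
    best_w <- NULL; best_loss <- NULL
    trace <- list()
    wait <- 0L
    gen <- 0L
    repeat {
      gen <- gen + 1L
      losses <- lapply(seq_len(P), function(i)
        evaluate_candidate(pop[i, ], problem))
      ord <- lexical_order(losses)
      gb <- ord[1]
      improved <- is.null(best_loss) ||
        lexical_compare(losses[[gb]], best_loss) > 0
      if (improved) {
        best_w <- pop[gb, ]; best_loss <- losses[[gb]]; wait <- 0L
      } else wait <- wait + 1L
      trace[[gen]] <- best_loss
      if (gen >= ga$max_generations || wait >= ga$wait_generations) break
      ranks <- integer(P); ranks[ord] <- seq_len(P)
      pick <- function() {
        ij <- sample.int(P, 2)
        pop[ij[which.min(ranks[ij])], ]
      }
      np <- matrix(NA_real_, P, K)
      np[1, ] <- best_w  # elitism
      shrink <- (1 - gen / ga$max_generations)^2
      ops <- sample(names(ga$operator_mix), P - 1, replace = TRUE,
                    prob = ga$operator_mix)
      for (i in 2:P) {
        p1 <- pick()
        np[i, ] <- switch(ops[i - 1],
          clone = p1,
          unif_mut = { g <- sample.int(K, 1)
                       p1[g] <- stats::runif(1, lo, hi); p1 },
          bound_mut = { g <- sample.int(K, 1)
                        p1[g] <- if (stats::runif(1) < 0.5) lo else hi; p1 },
          nonunif_mut = { g <- sample.int(K, 1)
                          p1[g] <- clamp(p1[g] + (stats::runif(1) - 0.5) *
                                           (hi - lo) * shrink); p1 },
          arith_xover = { u <- stats::runif(1); u * p1 + (1 - u) * pick() },
          heur_xover = clamp(best_w + stats::runif(1) * (best_w - p1)),
          resample = stats::runif(K, lo, hi))
      }
      pop <- np
    }
    list(weights = best_w, loss = best_loss, generations = gen,
         trace = trace)
  })
}

#' Longitudinal genetic matching
#'
#' For each risk set in time order, assembles the matching variables
#' (the ten matching covariates at the risk-set interval, plus the Cox
#' proxied propensity score unless `include_ps = "none"`), whitens them by
#' the within-risk-set sample covariance, optimizes the diagonal distance
#' weights with [evolve_weights()], and 1:1 nearest-neighbour matches with
#' replacement and ties under the optimized distance. Balance inside the
#' loss is assessed on the ten covariates (the propensity score column is
#' added when `include_ps = "distance+loss"`). Controls remain eligible at
#' later intervals, including as treated subjects.
#'
#' @param panel a `panel_data`.
#' @param td_model fitted `td_ps_model` (not needed when
#'   `include_ps = "none"`).
#' @param ga a [ga_config()]; `max_generations = 0` yields unweighted
#'   Mahalanobis risk-set matching.
#' @return A `matched_cohort` with a per-risk-set search `trace`
#'   attribute (generations used, final loss, weights).
#' @export
match_genetic <- function(panel, td_model = NULL, ga = ga_config()) {
  cfg <- panel$config
  mvars <- cfg$matching_covariates
  use_ps <- ga$include_ps != "none"
  if (use_ps && is.null(td_model))
    stop("td_model is required unless include_ps = 'none'")
  lp <- if (use_ps) td_linear_predictor(td_model, panel)
  specs <- cfg$covariates
  names(specs) <- vapply(specs, `[[`, "", "name")
  binary <- vapply(specs[mvars], is_binary_spec, TRUE)
  rs <- build_risk_sets(panel)
  out <- list(); trace <- list(); unmatched <- integer()
  for (r in rs) {
    if (!length(r$controls)) {
      warning("risk set at interval ", r$interval,
              " has no controls; its treated subjects are unmatched")
      unmatched <- c(unmatched, r$treated)
      next
    }
    members <- c(r$treated, r$controls)
    Mm <- x_at(panel$X, r$interval)[members, mvars, drop = FALSE]
    # the proxied PS is the hazard-scale score exp(beta'x): unlike the linear
    # predictor it is not exactly collinear with the covariate columns, so it
    # adds a usable matching direction (rescaled for numerical stability;
    # whitening removes the scale anyway)
    if (use_ps)
      Mm <- cbind(Mm, .ps = exp(lp[members, r$interval] -
                                  max(lp[, r$interval])))
    bal <- if (ga$include_ps == "distance+loss") Mm
           else Mm[, mvars, drop = FALSE]
    bbin <- binary
    if (ga$include_ps == "distance+loss") bbin <- c(bbin, .ps = FALSE)
    prob <- risk_set_problem(Mm, length(r$treated), bal,
                             bbin[colnames(bal)], ga, r$interval)
    if (ga$max_generations == 0) {
      w <- rep(1, ncol(Mm))
      tr <- list(weights = w, loss = NULL, generations = 0L)
    } else {
      tr <- evolve_weights(prob, ga)
      w <- tr$weights
    }
    m <- weighted_nn_match(prob$Yt, prob$Yc, w, ga$tie_tol)
    out[[length(out) + 1]] <- data.frame(
      treated_id = r$treated[m$t], control_id = r$controls[m$c],
      interval = r$interval, weight = m$weight)
    trace[[as.character(r$interval)]] <-
      tr[c("weights", "loss", "generations")]
  }
  pairs <- do.call(rbind, out)
  ch <- new_matched_cohort(pairs, "genmatch", panel$replicate_id, unmatched)
  attr(ch, "trace") <- trace
  ch
}
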