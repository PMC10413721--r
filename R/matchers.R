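## Risk-set construction and 1:1 nearest-neighbour matchers, with
## replacement and ties (tied controls share weight 1/k).

#' Build per-interval risk sets
#'
#' A risk set at interval t contains the subjects newly treated at t and,
#' as potential controls, every subject not yet treated at the start of t
#' (treated strictly later, or never). Only intervals with at least one
#' newly treated subject yield a risk set.
#'
#' @param panel a `panel_data` object.
#' @return List of `risk_set` objects (interval, treated, controls).
#' @export
build_risk_sets <- function(panel) {
  ti <- panel$treat_interval
  if (all(is.na(ti))) {
    warning("no treated subjects in panel; returning empty risk-set list")
    return(list())
  }
  lapply(sort(unique(ti[!is.na(ti)])), function(t) {
    structure(list(interval = t,
                   treated = which(!is.na(ti) & ti == t),
                   controls = which(is.na(ti) | ti > t)),
              class = "risk_set")
  })
}

#' @export
print.risk_set <- function(x, ...) {
  cat("Risk set at interval ", x$interval, ": ", length(x$treated),
      " treated, ", length(x$controls), " controls\n", sep = "")
  invisible(x)
}

## 1-d nearest neighbours with replacement and exact ties.
## Returns data.frame(t = treated index, c = control index, weight), where
## a treated unit with k tied nearest controls contributes k rows of
## weight 1/k.
nn_with_ties <- function(treated_scores, control_scores, tol = 1e-12) {
  nt <- length(treated_scores); nc <- length(control_scores)
  stopifnot(nt >= 1, nc >= 1)
  o <- order(control_scores)
  s <- control_scores[o]
  pos <- findInterval(treated_scores, s)
  lo <- pmin(pmax(pos, 1L), nc)
  hi <- pmin(pos + 1L, nc)
  dmin <- pmin(abs(treated_scores - s[lo]), abs(treated_scores - s[hi]))
  left <- findInterval(treated_scores - dmin - tol, s) + 1L
  right <- findInterval(treated_scores + dmin + tol, s)
  k <- right - left + 1L
  idx <- sequence(k) - 1L + rep(left, k)
  data.frame(t = rep(seq_len(nt), k), c = o[idx], weight = rep(1 / k, k))
}

new_matched_cohort <- function(pairs, method, replicate_id = NA_integer_,
                               unmatched = integer()) {
  structure(pairs, class = c("matched_cohort", "data.frame"),
            method = method, replicate_id = replicate_id,
            unmatched = unmatched)
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("Matched cohort (method: ", attr(x, "method"), ")\n", sep = "")
  cat("  ", length(unique(x$treated_id)), " treated subjects, ",
      nrow(x), " pairs, ", length(unique(x$control_id)),
      " distinct controls\n", sep = "")
  um <- attr(x, "unmatched")
  if (length(um)) cat("  unmatched treated subjects:", length(um), "\n")
  invisible(x)
}

#' 1:1 nearest-neighbour matching on the baseline propensity score
#'
#' Matches every ever-treated subject to the never-treated subject(s) with
#' the closest baseline propensity score, with replacement; exact ties are
#' all retained with weight 1/k. This estimator treats assignment as if it
#' happened at baseline, so the control pool is the never-treated subjects
#' and each pair is anchored at the treated subject's treatment interval
#' for outcome and balance evaluation.
#'
#' @param model a `baseline_ps_model`.
#' @param panel the corresponding `panel_data`.
#' @param tol absolute score-difference below which controls count as tied.
#' @return A `matched_cohort` data frame (treated_id, control_id,
#'   interval, weight).
#' @export
match_baseline_ps <- function(model, panel, tol = 1e-12) {
  ti <- panel$treat_interval
  treated <- which(!is.na(ti))
  controls <- which(is.na(ti))
  if (!length(controls)) stop("no never-treated subjects available as controls")
  ps <- model$fitted
  m <- nn_with_ties(ps[treated], ps[controls], tol)
  pairs <- data.frame(treated_id = treated[m$t],
                      control_id = controls[m$c],
                      interval = ti[treated[m$t]],
                      weight = m$weight)
  new_matched_cohort(pairs, "baseline_ps", panel$replicate_id)
}

#' Sequential risk-set matching on the time-dependent propensity score
#'
#' Iterates intervals in time order; within each risk set, every newly
#' treated subject is matched (with replacement and ties) to the
#' not-yet-treated subject(s) whose Cox linear predictor at that interval
#' is closest. Matched controls stay eligible at later intervals, including
#' as treated subjects at their own treatment date.
#'
#' @param model a `td_ps_model`.
#' @param panel the corresponding `panel_data`.
#' @param tol tie tolerance on the linear-predictor distance.
#' @return A `matched_cohort`; treated subjects in a risk set with no
#'   remaining controls are recorded in `attr(, "unmatched")`.
#' @export
match_td_ps <- function(model, panel, tol = 1e-12) {
  lp <- td_linear_predictor(model, panel)
  rs <- build_risk_sets(panel)
  out <- vector("list", length(rs))
  unmatched <- integer()
  for (i in seq_along(rs)) {
    r <- rs[[i]]
    if (!length(r$controls)) {
      warning("risk set at interval ", r$interval,
              " has no controls; its treated subjects are unmatched")
      unmatched <- c(unmatched, r$treated)
      next
    }
    m <- nn_with_ties(lp[r$treated, r$interval], lp[r$controls, r$interval],
                      tol)
    out[[i]] <- data.frame(treated_id = r$treated[m$t],
                           control_id = r$controls[m$c],
                           interval = r$interval,
                           weight = m$weight)
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  new_matched_cohort(pairs, "td_ps", panel$replicate_id, unmatched)
}
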