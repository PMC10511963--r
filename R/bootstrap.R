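#' Weighted block bootstrap for the matched DID estimator
#'
#' The estimator is decomposed into per-unit contributions (`c_j`, `d_j`,
#' see Details); each replicate resamples whole units (the block is a unit's
#' full time series) with replacement and recomputes
#' `sum(c_j*) / sum(d_j*)`. Matched-set weights stay frozen inside the
#' bootstrap: the refinement is treated as a component of the estimator, not
#' refitted per replicate (set `refit = TRUE` to refit the score model in
#' every replicate as an honesty check).
#'
#' @details For unit `j`, `c_j` sums the own outcome changes over `j`'s
#' treated matched events minus `weight * change` over `j`'s memberships in
#' other units' matched sets, and `d_j` counts `j`'s treated matched events;
#' the full-sample statistic `sum(c_j) / sum(d_j)` reproduces
#' [estimate_did()] exactly. Units are put in canonical (sorted id) order
#' before sampling, so the result is invariant to record ordering.
#' Replicates with no treated unit drawn (`sum(d*) = 0`) are redrawn and
#' counted; a warning is issued if they exceed 1% of `reps`.
#'
#' @param msets a `matched_sets` object with final weights.
#' @param panel the `cohort_panel`.
#' @param F lead at which to evaluate the estimator.
#' @param reps bootstrap replicates (>= 2); the reference design uses 1000.
#' @param seed integer seed controlling all resampling.
#' @param ci_mode `"percentile"` (default; 2.5/97.5 percentiles of the
#'   replicates) or `"normal"` (`estimate +- 1.96 se`, the asymptotic form).
#' @param refit if `TRUE`, refit the refinement model within each replicate
#'   (slow; requires `X` and `refinement_args`).
#' @param X,refinement_args covariate matrix and arguments for the refit
#'   (only used when `refit = TRUE`).
#' @return a `did_result` with `se`, `ci_low`, `ci_high` filled; attribute
#'   `replicates` holds the replicate statistics, attribute `n_redrawn` the
#'   number of degenerate draws discarded.
#' @export
block_bootstrap <- function(msets, panel, F = 0L, reps = 1000L,
                            seed = 1L, ci_mode = c("percentile", "normal"),
                            refit = FALSE, X = NULL,
                            refinement_args = list()) {
  ci_mode <- match.arg(ci_mode)
  if (reps < 2L) stop("reps must be at least 2")
  res <- estimate_did(msets, panel, F = F)
  dec <- did_unit_decomposition(msets, panel, F = F)
  n <- length(dec$units)
  stat <- numeric(reps)
  n_redrawn <- 0L
  set.seed(seed)
  if (!refit) {
    csum <- dec$c; dsum <- dec$d
    for (r in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        dstar <- sum(dsum[idx])
        if (dstar > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      stat[r] <- sum(csum[idx]) / dstar
    }
  } else {
    if (is.null(X)) stop("refit = TRUE requires the covariate matrix X")
    for (r in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        bs <- resample_matched_sets(msets, dec$units[idx])
        est <- tryCatch({
          mod <- do.call(fit_refinement, c(list(bs, X), refinement_args))
          estimate_did(refine(bs, X, mod), panel, F = F)$estimate
        }, error = function(e) NA_real_)
        if (!is.na(est)) break
        n_redrawn <- n_redrawn + 1L
      }
      stat[r] <- est
    }
  }
  if (n_redrawn > 0.01 * reps) {
    warning(n_redrawn, " degenerate bootstrap draws redrawn (> 1% of reps)")
  }
  res$se <- stats::sd(stat)
  if (ci_mode == "percentile") {
    qs <- stats::quantile(stat, c(0.025, 0.975), names = FALSE)
    res$ci_low <- qs[1]; res$ci_high <- qs[2]
  } else {
    res$ci_low <- res$estimate - 1.96 * res$se
    res$ci_high <- res$estimate + 1.96 * res$se
  }
  res$ci_mode <- ci_mode
  res$reps <- as.integer(reps)
  attr(res, "replicates") <- stat
  attr(res, "n_redrawn") <- n_redrawn
  res
}

# Internal: rebuild a matched_sets object restricted to a resampled unit
# multiset (used only by the refit honesty check). Treated events of a unit
# drawn m times are repeated m times; members are kept with multiplicity in
# the weight renormalisation.
resample_matched_sets <- function(msets, unit_draw) {
  mult <- table(unit_draw)
  ev <- msets$events
  sets <- list()
  for (s in msets$sets) {
    mtreat <- mult[ev$unit_id[s$event_row]]
    if (is.na(mtreat) || mtreat == 0) next
    mmem <- as.numeric(mult[ev$unit_id[s$members]])
    mmem[is.na(mmem)] <- 0
    keep <- mmem > 0
    s$members <- s$members[keep]
    s$weights <- if (any(keep)) {
      w <- s$weights[keep] * mmem[keep]
      w / sum(w)
    } else numeric(0)
    sets <- c(sets, rep(list(s), mtreat))
  }
  msets$sets <- sets
  msets
}
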