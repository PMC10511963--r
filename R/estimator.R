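#' Matched difference-in-differences point estimate at lead F
#'
#' For each treated, matched event at `(i, t)` the contribution is the
#' unit's own outcome change from wave `t - 1` to wave `t + F` minus the
#' weighted average of the same change over its matched controls; the
#' estimate is the average contribution over treated, matched events.
#' Unmatched treated events are excluded and counted.
#'
#' @param msets a `matched_sets` object (refined or not).
#' @param panel the `cohort_panel` the events were coded from.
#' @param F lead (0 = transition wave).
#' @return object of class `did_result`: list with `direction`, `F`,
#'   `estimate`, `n_treated` (events entering the average), `n_unmatched`,
#'   `refinement`, and `se`/`ci_low`/`ci_high` set to `NA` until filled by
#'   [block_bootstrap()].
#' @export
estimate_did <- function(msets, panel, F = 0L) {
  stopifnot(inherits(msets, "matched_sets"), F >= 0L)
  Y <- panel_matrix(panel, "outcome")
  ev <- msets$events
  iu <- match(ev$unit_id, rownames(Y))
  chg <- Y[cbind(iu, ev$t + F + 1L)] - Y[cbind(iu, ev$t)]
  matched <- vapply(msets$sets, function(s) length(s$members) > 0L,
                    logical(1))
  if (!any(matched)) stop("no estimable events: every treated event is unmatched")
  contrib <- vapply(msets$sets[matched], function(s) {
    chg[s$event_row] - sum(s$weights * chg[s$members])
  }, numeric(1))
  if (anyNA(contrib)) {
    stop("missing outcome at t-1 or t+F for an event; ",
         "run apply_eligibility with leads >= F")
  }
  structure(list(direction = unique(ev$direction), F = as.integer(F),
                 estimate = mean(contrib),
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 n_treated = sum(matched),
                 n_unmatched = sum(!matched),
                 refinement = msets$refinement,
                 ci_mode = NA_character_, reps = NA_integer_),
            class = "did_result")
}

#' Unadjusted matched DID estimate
#'
#' Identical contrast to [estimate_did()] but on equal within-set weights,
#' regardless of any refinement applied to `msets`.
#'
#' @inheritParams estimate_did
#' @return a `did_result` with `refinement = "none"`.
#' @export
estimate_unadjusted <- function(msets, panel, F = 0L) {
  msets$sets <- lapply(msets$sets, function(s) {
    m <- length(s$members)
    if (m > 0L) s$weights <- rep(1 / m, m)
    s
  })
  msets$refinement <- "none"
  estimate_did(msets, panel, F = F)
}

#' @export
print.did_result <- function(x, digits = 3, ...) {
  cat(sprintf("DID^%s(F=%d, %s): %.*f",
              x$direction, x$F,
              if (x$refinement == "none") "unadjusted"
              else paste0("adjusted/", x$refinement),
              digits, x$estimate))
  if (!is.na(x$se)) {
    cat(sprintf("  SE %.*f  95%% CI [%.*f, %.*f] (%s, %d reps)",
                digits, x$se, digits, x$ci_low, digits, x$ci_high,
                x$ci_mode, x$reps))
  }
  cat(sprintf("\n  treated events: %d (unmatched excluded: %d)\n",
              x$n_treated, x$n_unmatched))
  invisible(x)
}

# Internal: per-unit decomposition of the estimator. For unit j,
#   c_j = sum over j's treated matched events of [own change]
#         - sum over j's matched-set memberships of [weight * change]
#   d_j = number of treated, matched events of j,
# so that sum(c) / sum(d) equals the point estimate exactly.
did_unit_decomposition <- function(msets, panel, F = 0L) {
  Y <- panel_matrix(panel, "outcome")
  ev <- msets$events
  iu <- match(ev$unit_id, rownames(Y))
  chg <- Y[cbind(iu, ev$t + F + 1L)] - Y[cbind(iu, ev$t)]
  units <- sort(unique(ev$unit_id))
  cj <- stats::setNames(numeric(length(units)), units)
  dj <- stats::setNames(numeric(length(units)), units)
  uidx <- match(ev$unit_id, units)
  matched <- msets$sets[vapply(msets$sets, function(s)
    length(s$members) > 0L, logical(1))]
  t_rows <- vapply(matched, `[[`, integer(1), "event_row")
  tadd <- rowsum(chg[t_rows], uidx[t_rows])
  cj[as.integer(rownames(tadd))] <- cj[as.integer(rownames(tadd))] + tadd
  dcnt <- rowsum(rep(1, length(t_rows)), uidx[t_rows])
  dj[as.integer(rownames(dcnt))] <- dcnt
  mem <- unlist(lapply(matched, `[[`, "members"))
  wts <- unlist(lapply(matched, `[[`, "weights"))
  if (length(mem)) {
    msub <- rowsum(wts * chg[mem], uidx[mem])
    cj[as.integer(rownames(msub))] <- cj[as.integer(rownames(msub))] - msub
  }
  list(units = units, c = cj, d = dj)
}
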