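#' Build exact treatment-history matched sets
#'
#' For every treated event at `(i, t)`, the matched set contains all control
#' events at the *same* wave `t` whose employment values over waves
#' `t - L .. t - 1` are identical to the treated unit's (the wave-`t` value
#' differs by construction: the treated unit transitions, the control keeps
#' the origin state). Initial weights are equal, `1 / |M_it|`. Treated
#' events with an empty matched set are flagged unmatched and excluded from
#' estimation.
#'
#' @param events event data.frame from [code_transitions()] filtered by
#'   [apply_eligibility()]; must contain both treated and control events of
#'   one direction.
#' @param panel a `cohort_panel`.
#' @param lags history length L (>= 1) to match on.
#' @return object of class `matched_sets`: list with `events` (with a
#'   `history` key column added), `sets` (per treated event: `event_row`,
#'   integer `members` indexing control rows of `events`, numeric
#'   `weights`), `lags`, `refinement` ("none"), `n_unmatched`.
#' @export
build_matched_sets <- function(events, panel, lags = 3L) {
  stopifnot(inherits(panel, "cohort_panel"), lags >= 1L, nrow(events) > 0L)
  if (length(unique(events$direction)) > 1L) {
    stop("events must be of a single direction; build sets per direction")
  }
  E <- panel_matrix(panel, "employed")
  units <- rownames(E)
  iu <- match(events$unit_id, units)
  hist_cols <- vapply(seq_len(lags), function(k) {
    v <- E[cbind(iu, events$t - k + 1L)]
    ifelse(is.na(v), "m", as.character(v))
  }, character(nrow(events)))
  hist_cols <- matrix(hist_cols, nrow = nrow(events))
  history <- apply(hist_cols, 1L, paste, collapse = "")
  events$history <- history

  cell <- paste(events$t, history, sep = "|")
  ctrl_rows <- which(!events$treated)
  ctrl_by_cell <- split(ctrl_rows, cell[ctrl_rows])
  treated_rows <- which(events$treated)

  sets <- lapply(treated_rows, function(r) {
    members <- ctrl_by_cell[[cell[r]]]
    if (is.null(members)) members <- integer(0)
    w <- if (length(members)) rep(1 / length(members), length(members))
         else numeric(0)
    list(event_row = r, members = members, weights = w)
  })
  structure(list(events = events, sets = sets, lags = lags,
                 refinement = "none",
                 n_unmatched = sum(vapply(sets, function(s)
                   length(s$members) == 0L, logical(1)))),
            class = "matched_sets")
}

#' @export
print.matched_sets <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat("matched_sets:", length(x$sets), "treated events (",
      x$n_unmatched, "unmatched ), direction",
      unique(x$events$direction), ", L =", x$lags, "\n")
  if (any(sizes > 0)) {
    cat("  matched-set size: median", stats::median(sizes[sizes > 0]),
        ", range", min(sizes[sizes > 0]), "-", max(sizes), "\n")
  }
  cat("  refinement:", x$refinement, "\n")
  invisible(x)
}

#' Dump matched sets as a delimited audit table
#'
#' @param msets a `matched_sets` object.
#' @param path output CSV path; `NULL` returns the data.frame.
#' @return data.frame with one row per (treated event, member) pair.
#' @export
write_matched_sets <- function(msets, path = NULL) {
  ev <- msets$events
  rows <- lapply(msets$sets, function(s) {
    if (length(s$members) == 0L) {
      return(data.frame(treated_unit = ev$unit_id[s$event_row],
                        t = ev$t[s$event_row], member = NA_character_,
                        weight = NA_real_, refinement = msets$refinement,
                        stringsAsFactors = FALSE))
    }
    data.frame(treated_unit = ev$unit_id[s$event_row],
               t = ev$t[s$event_row],
               member = ev$unit_id[s$members],
               weight = s$weights, refinement = msets$refinement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
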