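#' Code employment transitions into treated and control events
#'
#' For the *entry* direction a treated event is a person-wave with
#' `employed = 0` at wave `t - 1` and `employed = 1` at wave `t`; a control
#' event keeps `employed = 0` at both. For *exit* the origin state is
#' employment, the treated event moves to non-employment and the control
#' event stays employed. Person-waves whose origin state does not fit the
#' direction are excluded; person-waves with missing employment at either
#' wave are skipped. A unit may contribute events at several waves.
#'
#' @param panel a `cohort_panel`.
#' @param direction `"entry"` or `"exit"`.
#' @param window length-2 integer: first and last calendar year at which a
#'   transition may be treated (default 2012--2018).
#' @return data.frame of events (`unit_id`, `t`, `year`, `direction`,
#'   `treated`) with attribute `exclusions`, a named count vector.
#' @export
code_transitions <- function(panel, direction = c("entry", "exit"),
                             window = c(2012L, 2018L)) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "cohort_panel"),
            length(panel$wave_years) >= 2L)
  E <- panel_matrix(panel, "employed")
  units <- rownames(E)
  in_win <- which(panel$wave_years >= window[1] &
                    panel$wave_years <= window[2])
  in_win <- in_win[in_win >= 2L]  # need a t-1 wave
  origin <- if (direction == "entry") 0 else 1
  dest_treated <- 1 - origin
  out <- vector("list", length(in_win))
  n_missing <- 0L; n_wrong_origin <- 0L
  for (j in seq_along(in_win)) {
    tw <- in_win[j]                       # column index = wave_index + 1
    prev <- E[, tw - 1L]; now <- E[, tw]
    obs <- !is.na(prev) & !is.na(now)
    n_missing <- n_missing + sum(!obs)
    ok <- obs & prev == origin
    n_wrong_origin <- n_wrong_origin + sum(obs & prev != origin)
    if (!any(ok)) next
    out[[j]] <- data.frame(unit_id = units[ok],
                           t = tw - 1L,
                           year = panel$wave_years[tw],
                           direction = direction,
                           treated = now[ok] == dest_treated,
                           stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) {
    ev <- data.frame(unit_id = character(), t = integer(), year = integer(),
                     direction = character(), treated = logical())
  }
  ev <- ev[order(ev$t, ev$unit_id), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "exclusions") <- c(missing_employment = n_missing,
                              wrong_origin_state = n_wrong_origin)
  ev
}

#' Filter events to the consecutive-participation eligibility window
#'
#' Keeps events whose unit has non-missing employment *and* outcome at every
#' wave from `t - lags` through `t + leads` (the "L + 1 + F consecutive
#' waves" criterion), and, when an age variable is available, whose age at
#' the transition wave is at least `min_age`. The attribute `exclusions`
#' tallies the events removed at each sequential criterion, flowchart-style,
#' so that `kept + sum(exclusions) = input`.
#'
#' @param panel a `cohort_panel`.
#' @param events event data.frame from [code_transitions()].
#' @param lags number of pre-treatment waves that must be observed (L).
#' @param leads number of post-treatment waves that must be observed (F).
#' @param min_age minimum age at the transition wave; `NULL` disables.
#' @param age_var name of the age column (ignored when absent).
#' @return filtered events with attribute `exclusions`.
#' @export
apply_eligibility <- function(panel, events, lags = 3L, leads = 1L,
                              min_age = 65, age_var = "age") {
  stopifnot(lags >= 0L, leads >= 0L)
  if (nrow(events) == 0L) {
    attr(events, "exclusions") <- c(outside_wave_range = 0L,
                                    gap_in_participation = 0L,
                                    below_min_age = 0L)
    return(events)
  }
  W <- length(panel$wave_years)
  E <- panel_matrix(panel, "employed")
  Y <- panel_matrix(panel, "outcome")
  obs <- !is.na(E) & !is.na(Y)
  units <- rownames(E)
  iu <- match(events$unit_id, units)

  in_range <- events$t - lags >= 0L & events$t + leads <= W - 1L
  n_range <- sum(!in_range)
  keep1 <- which(in_range)

  full_obs <- rep(TRUE, length(keep1))
  for (off in seq.int(-lags, leads)) {
    full_obs <- full_obs &
      obs[cbind(iu[keep1], events$t[keep1] + off + 1L)]
  }
  n_gap <- sum(!full_obs)
  keep2 <- keep1[full_obs]

  n_age <- 0L
  keep3 <- keep2
  has_age <- !is.null(min_age) && age_var %in% names(panel$records)
  if (has_age && length(keep2)) {
    A <- panel_matrix(panel, age_var, respect_observed = FALSE)
    age_t <- A[cbind(iu[keep2], events$t[keep2] + 1L)]
    ok_age <- !is.na(age_t) & age_t >= min_age
    n_age <- sum(!ok_age)
    keep3 <- keep2[ok_age]
  }
  out <- events[keep3, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(outside_wave_range = n_range,
                               gap_in_participation = n_gap,
                               below_min_age = n_age)
  out
}

#' Harmonise monetary amounts into thousands of a reference currency
#'
#' Applies an inflation deflator and a purchasing-power-parity factor, then
#' rescales to thousands: `value * deflator / ppp_factor / 1000`. The map is
#' strictly monotone, so downstream tertile ranks are unaffected by the
#' choice of factors.
#'
#' @param values numeric amounts in the source currency.
#' @param ppp_factor positive PPP conversion factor (source units per
#'   reference unit).
#' @param deflator positive inflation adjustment multiplier.
#' @return amounts in thousands of the reference currency.
#' @export
harmonise_currency <- function(values, ppp_factor, deflator = 1) {
  if (!is.numeric(ppp_factor) || ppp_factor <= 0) {
    stop("ppp_factor must be a positive number")
  }
  if (!is.numeric(deflator) || deflator <= 0) {
    stop("deflator must be a positive number")
  }
  values * deflator / ppp_factor / 1000
}
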