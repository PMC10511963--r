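# Independent brute-force oracles for matching and the DID contrast.
# These work on a plain long data.frame ("df" with unit, t, employed,
# outcome columns) via literal loops over the definitions, sharing no code
# with the package internals they are used to check.

# random long panel: n units x W waves, persistent employment, integer
# outcomes, optional missingness holes
random_panel_df <- function(n_units, n_waves, p_miss = 0, seed = 1) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_units)) {
    emp <- numeric(n_waves)
    emp[1] <- rbinom(1, 1, 0.5)
    for (w in 2:n_waves) {
      emp[w] <- if (runif(1) < 0.75) emp[w - 1] else 1 - emp[w - 1]
    }
    y <- pmin(30, pmax(0, round(rnorm(n_waves, 22, 4))))
    if (p_miss > 0) {
      hole <- runif(n_waves) < p_miss
      emp[hole] <- NA
      y[hole] <- NA
    }
    out[[i]] <- data.frame(unit = sprintf("u%03d", i),
                           t = seq_len(n_waves) - 1L,
                           employed = emp, outcome = y,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# value lookup (NA when the person-wave is absent)
df_val <- function(df, unit, t, field) {
  v <- df[[field]][df$unit == unit & df$t == t]
  if (length(v) == 0) NA else v
}

# literal event coding + eligibility: loops over every unit and wave
oracle_events <- function(df, direction, L, Fmax, window_t) {
  units <- unique(df$unit)
  origin <- if (direction == "entry") 0 else 1
  ev <- list()
  for (i in units) {
    for (t in window_t) {
      prev <- df_val(df, i, t - 1, "employed")
      now <- df_val(df, i, t, "employed")
      if (is.na(prev) || is.na(now) || prev != origin) next
      ok <- TRUE
      for (s in (t - L):(t + Fmax)) {
        if (is.na(df_val(df, i, s, "employed")) ||
            is.na(df_val(df, i, s, "outcome"))) ok <- FALSE
      }
      if (!ok) next
      ev[[length(ev) + 1L]] <- list(unit = i, t = t,
                                    treated = (now != origin))
    }
  }
  ev
}

# literal matched sets: for each treated event, every control event at the
# same wave with identical employment at t-L .. t-1
oracle_matched_sets <- function(df, direction, L, Fmax, window_t) {
  ev <- oracle_events(df, direction, L, Fmax, window_t)
  treated <- Filter(function(e) e$treated, ev)
  controls <- Filter(function(e) !e$treated, ev)
  lapply(treated, function(e) {
    members <- character()
    for (cc in controls) {
      if (cc$t != e$t) next
      same <- TRUE
      for (k in 1:L) {
        a <- df_val(df, e$unit, e$t - k, "employed")
        b <- df_val(df, cc$unit, cc$t - k, "employed")
        if (is.na(a) || is.na(b) || a != b) same <- FALSE
      }
      if (same) members <- c(members, cc$unit)
    }
    list(unit = e$unit, t = e$t, members = sort(members))
  })
}

# literal equal-weight DID contrast at lead F over the oracle matched sets
oracle_did <- function(df, sets, F) {
  contribs <- numeric(0)
  for (s in sets) {
    if (length(s$members) == 0) next
    own <- df_val(df, s$unit, s$t + F, "outcome") -
      df_val(df, s$unit, s$t - 1, "outcome")
    ctrl <- 0
    for (m in s$members) {
      ctrl <- ctrl + (df_val(df, m, s$t + F, "outcome") -
                        df_val(df, m, s$t - 1, "outcome")) /
        length(s$members)
    }
    contribs <- c(contribs, own - ctrl)
  }
  if (length(contribs) == 0) NA_real_ else mean(contribs)
}

# package-side panel from the same data.frame (2006-biennial year coding)
panel_from_df <- function(df) {
  yrs <- seq(2006L, by = 2L, length.out = max(df$t) + 1L)
  rec <- data.frame(unit_id = df$unit, year = yrs[df$t + 1L],
                    employed = df$employed, outcome = df$outcome,
                    stringsAsFactors = FALSE)
  as_panel(rec, wave_years = yrs)
}

# package-side matched sets in oracle shape, for set-equality comparison
msets_to_oracle_shape <- function(msets) {
  ev <- msets$events
  out <- lapply(msets$sets, function(s) {
    list(unit = ev$unit_id[s$event_row], t = ev$t[s$event_row],
         members = sort(ev$unit_id[s$members]))
  })
  out[order(vapply(out, function(e) paste(e$t, e$unit), ""))]
}
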