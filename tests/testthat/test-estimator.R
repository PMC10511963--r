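# hand-built panel: one treated entry event plus controls with chosen
# outcome paths; waves 2006..2014, event at t = 3 (2012)
did_toy_panel <- function(treated_path, control_paths) {
  yrs <- seq(2006, 2014, 2)
  paths <- c(list(treated_path), control_paths)
  n <- length(paths)
  ids <- c("T1", sprintf("C%d", seq_len(n - 1)))
  rec <- data.frame(unit_id = rep(ids, each = 5),
                    year = rep(yrs, n),
                    employed = c(c(0, 0, 0, 1, 1),
                                 rep(c(0, 0, 0, 0, 0), n - 1)),
                    outcome = unlist(paths),
                    stringsAsFactors = FALSE)
  as_panel(rec, wave_years = yrs)
}

toy_fit <- function(p, F = 0) {
  ev <- apply_eligibility(p, code_transitions(p, "entry",
                                              window = c(2012, 2012)),
                          lags = 3, leads = 1, min_age = NULL)
  ms <- build_matched_sets(ev, p, lags = 3)
  estimate_did(ms, p, F = F)
}

test_that("single treated event with one control gives the exact contrast", {
  # treated change +2 (t-1=24 -> t=26), control change +1 (24 -> 25)
  p <- did_toy_panel(c(22, 23, 24, 26, 27), list(c(22, 23, 24, 25, 25)))
  r <- toy_fit(p)
  expect_equal(r$estimate, 2 - 1)
  expect_equal(r$n_treated, 1L)
  expect_equal(r$n_unmatched, 0L)
})

test_that("equal-weight controls give the arithmetic mean contrast", {
  # treated change +3; two controls change 0 and +2 -> 3 - 1 = 2
  p <- did_toy_panel(c(20, 21, 22, 25, 25),
                     list(c(20, 21, 22, 22, 22),
                          c(20, 21, 22, 24, 24)))
  r <- toy_fit(p)
  expect_equal(r$estimate, 3 - mean(c(0, 2)))
})

test_that("the estimate averages per-event contributions", {
  # two treated events at the same wave with contributions 1.0 and -0.5
  yrs <- seq(2006, 2014, 2)
  rec <- data.frame(
    unit_id = rep(c("T1", "T2", "C1"), each = 5),
    year = rep(yrs, 3),
    employed = c(0, 0, 0, 1, 1,  0, 0, 0, 1, 1,  0, 0, 0, 0, 0),
    outcome = c(20, 20, 20, 22, 22,      # change +2
                20, 20, 20, 20.5, 20,    # change +0.5
                20, 20, 20, 21, 21))     # control change +1
  p <- as_panel(rec)
  ev <- apply_eligibility(p, code_transitions(p, "entry",
                                              window = c(2012, 2012)),
                          lags = 3, leads = 1, min_age = NULL)
  ms <- build_matched_sets(ev, p, lags = 3)
  r <- estimate_did(ms, p, F = 0)
  expect_equal(r$estimate, mean(c(2 - 1, 0.5 - 1)))
  expect_equal(r$estimate, 0.25)
})

test_that("base period is always t-1, evaluated at lead F", {
  p <- did_toy_panel(c(20, 21, 22, 25, 28),
                     list(c(20, 21, 22, 23, 24)))
  expect_equal(toy_fit(p, F = 0)$estimate, (25 - 22) - (23 - 22))
  expect_equal(toy_fit(p, F = 1)$estimate, (28 - 22) - (24 - 22))
})

test_that("estimates are location equivariant", {
  df <- random_panel_df(26, 6, seed = 17)
  p <- panel_from_df(df)
  ev <- apply_eligibility(p, code_transitions(p, "entry",
                                              window = c(2012, 2016)),
                          lags = 3, leads = 0, min_age = NULL)
  ms <- build_matched_sets(ev, p, lags = 3)
  base <- estimate_did(ms, p, F = 0)$estimate

  shifted <- p
  shifted$records$outcome <- shifted$records$outcome + 5
  shifted$instrument_range <- c(0, 40)
  expect_equal(estimate_did(ms, shifted, F = 0)$estimate, base)

  # adding c to a treated unit's outcomes from its event wave onward moves
  # the estimate by exactly c / n_treated for that event
  one <- did_toy_panel(c(20, 21, 22, 24, 24),
                       list(c(20, 21, 22, 23, 23)))
  b0 <- toy_fit(one)$estimate
  bumped <- one
  idx <- bumped$records$unit_id == "T1" & bumped$records$year >= 2012
  bumped$records$outcome[idx] <- bumped$records$outcome[idx] + 3
  expect_equal(toy_fit(bumped)$estimate, b0 + 3)
})

test_that("unadjusted equals adjusted when sets have one control", {
  p <- did_toy_panel(c(22, 23, 24, 26, 27), list(c(22, 23, 24, 25, 25)))
  ev <- apply_eligibility(p, code_transitions(p, "entry",
                                              window = c(2012, 2012)),
                          lags = 3, leads = 1, min_age = NULL)
  ms <- build_matched_sets(ev, p, lags = 3)
  spec <- covariate_spec(time_varying = "outcome",
                         tertile_vars = character())
  X <- build_covariates(p, ms$events, spec, lags = 3)
  for (method in c("mahalanobis", "ps_weight")) {
    model <- suppressWarnings(fit_refinement(ms, X, method))
    ref <- suppressWarnings(refine(ms, X, model))
    expect_equal(estimate_did(ref, p, F = 0)$estimate,
                 estimate_unadjusted(ref, p, F = 0)$estimate)
  }
})

test_that("estimator matches the literal brute-force loop on random panels", {
  for (seed in c(2, 8, 14)) {
    df <- random_panel_df(40, 6, p_miss = 0.1, seed = seed)
    p <- panel_from_df(df)
    for (dir in c("entry", "exit")) {
      ev <- apply_eligibility(p, code_transitions(p, dir,
                                                  window = c(2012, 2016)),
                              lags = 3, leads = 1, min_age = NULL)
      if (!any(ev$treated)) next
      ms <- build_matched_sets(ev, p, lags = 3)
      if (ms$n_unmatched == length(ms$sets)) next
      want <- oracle_did(df, oracle_matched_sets(df, dir, 3, 1, 3:4),
                         F = 1)
      got <- estimate_did(ms, p, F = 1)$estimate
      expect_equal(got, want, tolerance = 1e-12, info = paste(dir, seed))
    }
  }
})
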