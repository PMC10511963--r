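# waves 2006..2016 biennial; indices 0..5; default treatment window covers
# indices 3..5 (2012..2016)
three_wave_panel <- function(emp_list, years = seq(2006, 2016, 2)) {
  n <- length(emp_list)
  W <- length(years)
  rec <- data.frame(unit_id = rep(sprintf("u%02d", seq_len(n)), each = W),
                    year = rep(years, n),
                    employed = unlist(emp_list),
                    outcome = 25,
                    stringsAsFactors = FALSE)
  as_panel(rec, wave_years = years)
}

test_that("transition coding classifies all 8 length-3 histories correctly", {
  p <- make_fixture("histories8")
  # each of the 8 units has history (a, b, c) over waves 1..3 and then a
  # wave-4 value; enumerate expectations directly from the stored panel
  E <- matrix(p$records$employed, ncol = 6, byrow = TRUE)
  for (dir in c("entry", "exit")) {
    ev <- code_transitions(p, dir, window = c(2012, 2018))
    origin <- if (dir == "entry") 0 else 1
    got <- ev[ev$t == 4, ]
    for (i in seq_len(nrow(E))) {
      uid <- sprintf("f%02d", i)
      expected_event <- E[i, 4] == origin
      expect_equal(uid %in% got$unit_id, expected_event,
                   info = paste(dir, uid))
      if (expected_event) {
        expect_equal(got$treated[got$unit_id == uid],
                     E[i, 5] != origin, info = paste(dir, uid))
      }
    }
  }
})

test_that("a unit can be entry treated and exit treated at different waves", {
  # history (1, 0, 1) over three in-window waves: exit at the middle wave,
  # entry at the last
  p <- three_wave_panel(list(c(1, 1, 1, 1, 0, 1),
                             c(1, 1, 1, 1, 1, 1),
                             c(0, 0, 0, 0, 0, 1)))
  entry <- code_transitions(p, "entry")
  exit <- code_transitions(p, "exit")
  expect_true(any(entry$unit_id == "u01" & entry$t == 5 & entry$treated))
  expect_true(any(exit$unit_id == "u01" & exit$t == 4 & exit$treated))
  # treated and control are mutually exclusive and exhaust the events
  both <- rbind(entry, exit)
  expect_equal(anyDuplicated(both[c("unit_id", "t", "direction")]), 0L)
})

test_that("unobserved employment skips the event and is tallied", {
  p <- three_wave_panel(list(c(0, 0, 0, NA, 0, 0),
                             c(0, 0, 0, 0, 0, 0)))
  ev <- code_transitions(p, "entry")
  # u01 is skipped at t = 3 and t = 4 (NA at t or t-1)
  expect_false(any(ev$unit_id == "u01" & ev$t %in% c(3, 4)))
  expect_gte(attr(ev, "exclusions")[["missing_employment"]], 2)
})

test_that("eligibility keeps only fully observed windows and is monotone in L", {
  df <- random_panel_df(25, 6, p_miss = 0.25, seed = 7)
  p <- panel_from_df(df)
  for (dir in c("entry", "exit")) {
    ev <- code_transitions(p, dir, window = c(2012, 2016))
    e3 <- apply_eligibility(p, ev, lags = 3, leads = 1, min_age = NULL)
    e2 <- apply_eligibility(p, ev, lags = 2, leads = 1, min_age = NULL)
    expect_lte(nrow(e3), nrow(e2))      # stricter filter keeps fewer
    expect_lte(nrow(e3), nrow(ev))
    # conservation: kept + per-criterion exclusions = input
    expect_equal(nrow(e3) + sum(attr(e3, "exclusions")), nrow(ev))
    # every kept event is fully observed over t-3 .. t+1
    for (r in seq_len(nrow(e3))) {
      for (off in -3:1) {
        expect_false(is.na(df_val(df, e3$unit_id[r], e3$t[r] + off,
                                  "outcome")))
      }
    }
  }
})

test_that("minimum age at transition filters events", {
  rec <- expand.grid(unit_id = c("A", "B"), year = seq(2006, 2016, 2),
                     stringsAsFactors = FALSE)
  rec$employed <- ifelse(rec$unit_id == "A" & rec$year >= 2014, 1, 0)
  rec$outcome <- 25
  rec$age <- ifelse(rec$unit_id == "A", 52, 70) + (rec$year - 2006)
  p <- as_panel(rec)
  ev <- code_transitions(p, "entry")
  kept <- apply_eligibility(p, ev, lags = 3, leads = 1, min_age = 65)
  expect_false("A" %in% kept$unit_id)   # A is only 60 at the transition
  all_ages <- apply_eligibility(p, ev, lags = 3, leads = 1, min_age = NULL)
  expect_true("A" %in% all_ages$unit_id)
})

test_that("tertile ranks follow the equal-thirds rule and are monotone-invariant", {
  yrs <- c(2006, 2008)
  rec <- data.frame(unit_id = sprintf("u%d", 1:6),
                    year = 2006, employed = 0, outcome = 20,
                    income = c(1, 2, 3, 4, 5, 6))
  rec2 <- rec; rec2$year <- 2008; rec2$employed <- c(0, 0, 0, 1, 1, 1)
  p <- as_panel(rbind(rec, rec2), wave_years = yrs)
  ev <- code_transitions(p, "entry", window = c(2008, 2008))
  ev <- apply_eligibility(p, ev, lags = 1, leads = 0, min_age = NULL)
  spec <- covariate_spec(time_varying = c("income"),
                         tertile_vars = "income")
  X <- build_covariates(p, ev, spec, lags = 1)
  ranks <- X[order(ev$unit_id), "income.l1"]
  expect_equal(unname(ranks), c(1, 1, 2, 2, 3, 3))

  # strictly monotone transform leaves the ranks unchanged
  p2 <- p
  p2$records$income <- exp(p2$records$income)
  X2 <- build_covariates(p2, ev, spec, lags = 1)
  expect_equal(X2[, "income.l1"], X[, "income.l1"])
})

test_that("missing covariates get value 0 plus a 0/1 indicator", {
  yrs <- seq(2006, 2012, 2)
  rec <- expand.grid(unit_id = c("A", "B", "C"), year = yrs,
                     stringsAsFactors = FALSE)
  rec$employed <- ifelse(rec$unit_id == "A" & rec$year == 2012, 1, 0)
  rec$outcome <- 22
  rec$health <- 3
  rec$health[rec$unit_id == "A" & rec$year == 2008] <- NA  # lag 2 of t=3
  p <- as_panel(rec, wave_years = yrs)
  ev <- code_transitions(p, "entry", window = c(2012, 2012))
  ev <- apply_eligibility(p, ev, lags = 3, leads = 0, min_age = NULL)
  spec <- covariate_spec(time_varying = "health", tertile_vars = character())
  X <- build_covariates(p, ev, spec, lags = 3)
  a <- which(ev$unit_id == "A")
  expect_equal(unname(X[a, "health.l2"]), 0)
  expect_equal(unname(X[a, "health.l2.obs"]), 0)
  b <- which(ev$unit_id == "B")
  expect_equal(unname(X[b, "health.l2"]), 3)
  expect_equal(unname(X[b, "health.l2.obs"]), 1)
})

test_that("covariate slot count is lags x varying variables before encoding", {
  df <- random_panel_df(12, 6, seed = 3)
  df$h <- rnorm(nrow(df)); df$inc <- exp(rnorm(nrow(df)))
  p <- panel_from_df(df)
  p$records$h <- df$h[match(paste(p$records$unit_id, p$records$wave_index),
                            paste(df$unit, df$t))]
  p$records$inc <- df$inc[match(paste(p$records$unit_id,
                                      p$records$wave_index),
                                paste(df$unit, df$t))]
  ev <- code_transitions(p, "entry", window = c(2012, 2016))
  ev <- apply_eligibility(p, ev, lags = 3, leads = 0, min_age = NULL)
  spec <- covariate_spec(time_varying = c("h", "inc", "outcome"),
                         tertile_vars = "inc")
  X <- build_covariates(p, ev, spec, lags = 3)
  info <- attr(X, "feature_info")
  expect_equal(sum(info$type == "value"), 3 * 3)  # 3 vars x 3 lags
})

test_that("an all-missing covariate is a hard error naming the variable", {
  df <- random_panel_df(8, 6, seed = 5)
  p <- panel_from_df(df)
  p$records$ghost <- NA_real_
  ev <- code_transitions(p, "entry", window = c(2012, 2016))
  ev <- apply_eligibility(p, ev, lags = 2, leads = 0, min_age = NULL)
  spec <- covariate_spec(time_varying = "ghost", tertile_vars = character())
  expect_error(build_covariates(p, ev, spec, lags = 2),
               "'ghost' is missing for every event")
})

test_that("currency harmonisation scales exactly and preserves order", {
  expect_equal(harmonise_currency(1e6, ppp_factor = 1000), 1)
  expect_equal(harmonise_currency(c(2, 4), 1, deflator = 1.1),
               c(2, 4) * 1.1 / 1000)
  v <- c(5, 1, 9, 3)
  expect_equal(order(harmonise_currency(v, 850, 1.27)), order(v))
  expect_error(harmonise_currency(1, ppp_factor = 0), "positive")
  expect_error(harmonise_currency(1, 1, deflator = -1), "positive")
})
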