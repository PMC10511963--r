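# small helper: matched sets + covariates from a fixture or random panel
prep_sets <- function(p, window = c(2012, 2016), lags = 3, leads = 1,
                      spec = NULL) {
  ev <- apply_eligibility(p, code_transitions(p, "entry", window = window),
                          lags = lags, leads = leads, min_age = NULL)
  ms <- build_matched_sets(ev, p, lags = lags)
  if (is.null(spec)) {
    spec <- covariate_spec(time_varying = "outcome",
                           tertile_vars = character())
  }
  X <- build_covariates(p, ms$events, spec, lags = lags)
  list(ms = ms, X = X)
}

test_that("every method leaves nonnegative weights summing to one per set", {
  df <- random_panel_df(28, 6, seed = 11)
  p <- panel_from_df(df)
  pr <- prep_sets(p)
  for (method in c("none", "mahalanobis", "ps_match", "ps_weight",
                   "cbps_weight")) {
    model <- suppressWarnings(fit_refinement(pr$ms, pr$X, method,
                                             size_match = 2))
    ref <- refine(pr$ms, pr$X, model)
    expect_equal(ref$refinement, method)
    for (s in ref$sets) {
      if (length(s$members) == 0) next
      expect_true(all(s$weights >= 0), info = method)
      expect_equal(sum(s$weights), 1, info = method)
    }
  }
})

test_that("a single control gets weight one under every method", {
  p <- make_fixture("tie")
  # drop one control so the set has exactly one member
  rec <- p$records[p$records$unit_id != "f03", ]
  p1 <- as_panel(rec, wave_years = p$wave_years)
  spec <- covariate_spec(time_varying = c("health", "outcome"),
                         tertile_vars = character())
  pr <- prep_sets(p1, window = c(2014, 2014), spec = spec)
  for (method in c("none", "mahalanobis", "ps_match", "ps_weight",
                   "cbps_weight")) {
    model <- suppressWarnings(fit_refinement(pr$ms, pr$X, method))
    ref <- suppressWarnings(refine(pr$ms, pr$X, model))
    expect_equal(ref$sets[[1]]$weights, 1, info = method)
  }
})

test_that("identical controls get equal weights (symmetry)", {
  yrs <- seq(2006, 2014, 2)
  rec <- expand.grid(unit_id = c("T1", "C1", "C2"), year = yrs,
                     stringsAsFactors = FALSE)
  rec$employed <- ifelse(rec$unit_id == "T1" & rec$year == 2012, 1, 0)
  rec$outcome <- 22
  rec$health <- ifelse(rec$unit_id == "T1", 4, 3)
  p <- as_panel(rec, wave_years = yrs)
  spec <- covariate_spec(time_varying = "health", tertile_vars = character())
  pr <- prep_sets(p, window = c(2012, 2012), spec = spec)
  for (method in c("mahalanobis", "ps_match", "ps_weight", "cbps_weight")) {
    model <- suppressWarnings(fit_refinement(pr$ms, pr$X, method,
                                             size_match = 2))
    ref <- suppressWarnings(refine(pr$ms, pr$X, model))
    w <- ref$sets[[1]]$weights
    expect_equal(w, rep(0.5, 2), info = method)
  }
})

test_that("odds weighting reproduces the hand-computed example", {
  # two controls with fitted scores 0.8 and 0.2: odds 4 and 0.25,
  # normalised weights 0.941 and 0.059
  ev <- data.frame(unit_id = c("T", "C1", "C2"), t = 3, year = 2012,
                   direction = "entry", treated = c(TRUE, FALSE, FALSE),
                   stringsAsFactors = FALSE)
  ms <- structure(list(events = ev,
                       sets = list(list(event_row = 1L, members = 2:3,
                                        weights = c(0.5, 0.5))),
                       lags = 3, refinement = "none", n_unmatched = 0L),
                  class = "matched_sets")
  X <- matrix(c(0, 1, -1), ncol = 1,
              dimnames = list(NULL, "z"))
  model <- structure(list(method = "ps_weight", size_match = 5L,
                          keep = TRUE, center = 0, scale = 1,
                          coefficients = c(0, qlogis(0.8))),
                     class = "refinement_model")
  ref <- refine(ms, X, model)
  w <- ref$sets[[1]]$weights
  expect_equal(w, c(4 / 4.25, 0.25 / 4.25), tolerance = 1e-10)
  expect_equal(round(w, 3), c(0.941, 0.059))
})

test_that("refinement is idempotent given a fitted model", {
  df <- random_panel_df(24, 6, seed = 21)
  p <- panel_from_df(df)
  pr <- prep_sets(p)
  for (method in c("mahalanobis", "ps_match", "ps_weight", "cbps_weight")) {
    model <- suppressWarnings(fit_refinement(pr$ms, pr$X, method,
                                             size_match = 2))
    once <- refine(pr$ms, pr$X, model)
    twice <- refine(once, pr$X, model)
    expect_identical(lapply(once$sets, `[[`, "weights"),
                     lapply(twice$sets, `[[`, "weights"), info = method)
  }
})

test_that("nearest-J ties break deterministically by unit id", {
  p <- make_fixture("tie")
  spec <- covariate_spec(time_varying = c("health", "income", "asset"),
                         tertile_vars = character())
  pr <- prep_sets(p, window = c(2014, 2014), spec = spec)
  model <- suppressWarnings(fit_refinement(pr$ms, pr$X, "mahalanobis",
                                           size_match = 1))
  ref <- refine(pr$ms, pr$X, model)
  kept <- pr$ms$events$unit_id[ref$sets[[1]]$members]
  expect_equal(kept, "f02")             # the lower unit id of the tied pair
  # repeated runs agree
  ref2 <- refine(pr$ms, pr$X, model)
  expect_identical(ref$sets, ref2$sets)
})

test_that("CBPS coefficients vanish when groups share a distribution", {
  set.seed(31)
  n <- 4000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, 0.3)                # assignment ignores X
  th <- fit_cbps(y, X)
  expect_lt(max(abs(th[-1])), 0.1)
  expect_equal(unname(plogis(th[1])), 0.3, tolerance = 0.05)
})

test_that("CBPS enforces inverse-propensity-weighted balance on confounded data", {
  set.seed(32)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.4))
  eta <- -1 + 0.9 * X[, 1] - 0.8 * X[, 2] + 1.1 * X[, 3]
  y <- rbinom(n, 1, plogis(eta))
  smd_raw <- vapply(1:3, function(j) {
    (mean(X[y == 1, j]) - mean(X[y == 0, j])) / sd(X[y == 1, j])
  }, numeric(1))
  expect_gt(max(abs(smd_raw)), 0.3)     # confounding is real
  th <- fit_cbps(y, X)
  p_hat <- plogis(drop(cbind(1, X) %*% th))
  wt <- ifelse(y == 1, 1 / p_hat, 1 / (1 - p_hat))
  smd_w <- vapply(1:3, function(j) {
    m1 <- weighted.mean(X[y == 1, j], wt[y == 1])
    m0 <- weighted.mean(X[y == 0, j], wt[y == 0])
    (m1 - m0) / sd(X[y == 1, j])
  }, numeric(1))
  expect_lt(max(abs(smd_w)), 0.05)      # balanced after weighting
  # with equal total weight on both sides (just-identified intercept moment)
  expect_equal(sum(wt[y == 1]), sum(wt[y == 0]), tolerance = 1e-4)
})

test_that("CBPS equals the MLE weighting when the score model is correct", {
  set.seed(33)
  n <- 30000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * X[, 1] - 0.4 * X[, 2]))
  th_cbps <- fit_cbps(y, X)
  th_mle <- suppressWarnings(
    glm.fit(cbind(1, scale(X)), y, family = binomial())$coefficients)
  # map MLE back to raw scale for comparison
  b <- th_mle[-1] / attr(scale(X), "scaled:scale")
  th_mle_raw <- c(th_mle[1] - sum(attr(scale(X), "scaled:center") * b), b)
  expect_equal(unname(th_cbps), unname(th_mle_raw), tolerance = 0.08)
})

test_that("separable groups yield a boundary warning, not silent nonsense", {
  set.seed(34)
  x <- c(rnorm(60, 4), rnorm(60, -4))   # complete separation on x
  y <- rep(c(1, 0), each = 60)
  w <- capture_warnings(fit_cbps(y, cbind(x = x)))
  expect_true(any(grepl("separable|boundary|not exact", w)))
})

test_that("constant covariate columns are dropped with a warning", {
  set.seed(35)
  X <- cbind(good = rnorm(200), flat = 1)
  y <- rbinom(200, 1, 0.5)
  expect_warning(fit_cbps(y, X), "constant covariate")
})
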