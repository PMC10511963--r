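#' Parameterise the synthetic ageing-cohort data-generating process
#'
#' Emulates the structure of a biennial ageing panel (KLoSA/HRS-like): a
#' two-state employment Markov chain with age-declining retention,
#' covariates with documented dependencies (education drives health, income,
#' asset and occupation), a bounded integer cognitive score with age-related
#' decline, additive treatment effects at the transition wave, confounded
#' selection into transitions, absorbing attrition and item missingness.
#'
#' @param n_units cohort size.
#' @param wave_years survey years (default biennial 2006--2020).
#' @param age_range baseline age drawn uniformly on this integer range.
#' @param instrument `"mmse30"` (0--30) or `"tics27"` (0--27).
#' @param p_stay_employed probability an employed 65-year-old stays employed
#'   next wave; declines with age on the logit scale (-0.10 per year).
#' @param p_stay_out probability a non-employed 65-year-old stays out;
#'   entry odds decline with age (-0.08 per year).
#' @param tau_entry,tau_exit treatment effects (score points) at the
#'   transition wave (F = 0). Defaults mirror entry +0.65 / exit -0.44.
#' @param carryover_f1 effect one wave after the transition (F = 1); applied
#'   with a plus sign after entries and a minus sign after exits.
#' @param selection_strength scales the dependence of transition
#'   probabilities on self-reported health and the lagged cognitive score
#'   (active only when `confounding_on`).
#' @param confounding_on logical switch for confounded selection.
#' @param pretrend_violation slope (points per wave) of a treated-specific
#'   pre-trend, implemented through a latent treatment-proneness score that
#'   enters both the transition logits and the outcome slope; 0 = parallel
#'   trends hold.
#' @param attrition_rate per-wave probability of (absorbing) dropout.
#' @param covariate_missing_rate per-item missingness probability for
#'   income, asset, health and occupation.
#' @param seed integer seed; the whole panel is a deterministic function of
#'   the config.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_units = 2000L,
                            wave_years = seq(2006L, 2020L, by = 2L),
                            age_range = c(55L, 75L),
                            instrument = c("mmse30", "tics27"),
                            p_stay_employed = 0.80,
                            p_stay_out = 0.88,
                            tau_entry = 0.65,
                            tau_exit = -0.44,
                            carryover_f1 = 0,
                            selection_strength = 1,
                            confounding_on = TRUE,
                            pretrend_violation = 0,
                            attrition_rate = 0.03,
                            covariate_missing_rate = 0.05,
                            seed = 1L) {
  instrument <- match.arg(instrument)
  probs <- c(p_stay_employed = p_stay_employed, p_stay_out = p_stay_out,
             attrition_rate = attrition_rate,
             covariate_missing_rate = covariate_missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (length(wave_years) < 2L || any(diff(wave_years) <= 0)) {
    stop("wave_years must be an increasing vector of length >= 2")
  }
  structure(list(n_units = as.integer(n_units), wave_years = wave_years,
                 age_range = age_range, instrument = instrument,
                 p_stay_employed = p_stay_employed, p_stay_out = p_stay_out,
                 tau_entry = tau_entry, tau_exit = tau_exit,
                 carryover_f1 = carryover_f1,
                 selection_strength = selection_strength,
                 confounding_on = isTRUE(confounding_on),
                 pretrend_violation = pretrend_violation,
                 attrition_rate = attrition_rate,
                 covariate_missing_rate = covariate_missing_rate,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a synthetic cohort panel
#'
#' @param config a [scenario_config()].
#' @return list with `panel` (a `cohort_panel` with covariates `age`,
#'   `age2`, `female`, `education`, `spouse`, `birth1945`, `occupation`,
#'   `health`, `income`, `asset`) and `truth` (the config plus per-unit
#'   latent confounders and the realised transition indicator matrices).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_units
  yrs <- config$wave_years
  W <- length(yrs)
  step <- diff(yrs)[1]
  rng <- if (config$instrument == "mmse30") c(0, 30) else c(0, 27)
  base_level <- if (config$instrument == "mmse30") 21 else 14

  age0 <- sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE)
  female <- stats::rbinom(n, 1, 0.55)
  edu <- sample(1:4, n, replace = TRUE, prob = c(0.35, 0.20, 0.30, 0.15))
  spouse <- stats::rbinom(n, 1, 0.75)
  birth1945 <- as.integer(yrs[1] - age0 <= 1945)
  occupation <- pmin(3, pmax(1, round(1 + (edu - 1) * 0.6 +
                                        stats::rnorm(n, 0, 0.6))))
  health_base <- pmin(5, pmax(1, round(3 + 0.3 * (edu - 2.5) +
                                         stats::rnorm(n, 0, 0.9))))
  alpha <- stats::rnorm(n, 0, 2)
  prone <- stats::rnorm(n)  # latent treatment-proneness (pre-trend switch)
  s_on <- if (config$confounding_on) config$selection_strength else 0
  pt <- config$pretrend_violation

  emp <- matrix(NA_real_, n, W)
  cog <- matrix(NA_real_, n, W)
  entry_ind <- matrix(0, n, W)
  exit_ind <- matrix(0, n, W)
  health_w <- matrix(NA_real_, n, W)
  alive <- rep(TRUE, n)   # still participating (attrition is absorbing)
  dropout <- matrix(FALSE, n, W)

  for (w in seq_len(W)) {
    age <- age0 + step * (w - 1)
    health_w[, w] <- pmin(5, pmax(1, round(health_base +
                                             stats::rnorm(n, 0, 0.4))))
    if (w == 1L) {
      p_emp <- stats::plogis(0.6 + 0.3 * (edu - 2.5) - 0.08 * (age - 65))
      emp[, w] <- stats::rbinom(n, 1, p_emp)
    } else {
      zc <- (cog[, w - 1] - (base_level + 2)) / 3
      zc[is.na(zc)] <- 0
      sel <- s_on * (0.4 * (health_w[, w] - 3) + 0.8 * zc) +
        (pt > 0) * 0.7 * prone
      stay_logit <- stats::qlogis(config$p_stay_employed) -
        0.10 * (age - 65) + s_on * (0.4 * (health_w[, w] - 3) + 0.4 * zc) +
        (pt > 0) * 0.3 * prone
      enter_logit <- stats::qlogis(1 - config$p_stay_out) -
        0.08 * (age - 65) + sel
      p1 <- ifelse(emp[, w - 1] == 1, stats::plogis(stay_logit),
                   stats::plogis(enter_logit))
      p1[is.na(p1)] <- 0  # attrited units: path is wiped below anyway
      emp[, w] <- stats::rbinom(n, 1, p1)
      entry_ind[, w] <- as.numeric(!is.na(emp[, w - 1]) &
                                     emp[, w - 1] == 0 & emp[, w] == 1)
      exit_ind[, w] <- as.numeric(!is.na(emp[, w - 1]) &
                                    emp[, w - 1] == 1 & emp[, w] == 0)
    }
    eff <- config$tau_entry * entry_ind[, w] +
      config$tau_exit * exit_ind[, w]
    if (w >= 2L) {
      eff <- eff + config$carryover_f1 *
        (entry_ind[, w - 1] - exit_ind[, w - 1])
    }
    decline <- (0.12 + 0.02 * (3 - health_base)) * (age - 65)
    latent <- base_level + 0.8 * edu + 0.3 * (health_base - 3) + alpha -
      decline + pt * prone * (w - 1) + eff + stats::rnorm(n, 0, 1.5)
    cog[, w] <- pmin(rng[2], pmax(rng[1], round(latent)))

    if (w >= 2L) {
      drop_now <- alive & stats::runif(n) < config$attrition_rate
      alive <- alive & !drop_now
    }
    dropout[, w] <- !alive
  }

  # time-varying economics (depend on education and current employment)
  income <- exp(2 + 0.3 * matrix(edu, n, W) + 0.5 * emp +
                  matrix(stats::rnorm(n * W, 0, 0.7), n, W))
  asset <- exp(4 + 0.4 * matrix(edu, n, W) +
                 matrix(stats::rnorm(n * W, 0, 1.0), n, W))

  # item missingness, then attrition wipes whole person-waves
  mr <- config$covariate_missing_rate
  miss <- function(m) {
    m[matrix(stats::runif(n * W) < mr, n, W)] <- NA
    m
  }
  income <- miss(income); asset <- miss(asset); health_w <- miss(health_w)
  occ_w <- matrix(occupation, n, W)
  occ_w <- miss(occ_w)

  emp[dropout] <- NA
  cog[dropout] <- NA
  income[dropout] <- NA
  asset[dropout] <- NA
  health_w[dropout] <- NA
  occ_w[dropout] <- NA

  ids <- sprintf("u%05d", seq_len(n))
  rec <- data.frame(
    unit_id = rep(ids, W),
    year = rep(yrs, each = n),
    employed = as.vector(emp),
    outcome = as.vector(cog),
    age = rep(age0, W) + step * rep(seq_len(W) - 1L, each = n),
    age2 = (rep(age0, W) + step * rep(seq_len(W) - 1L, each = n))^2,
    female = rep(female, W),
    education = rep(edu, W),
    spouse = rep(spouse, W),
    birth1945 = rep(birth1945, W),
    occupation = as.vector(occ_w),
    health = as.vector(health_w),
    income = as.vector(income),
    asset = as.vector(asset),
    observed = rep(!logical(n), W) & !as.vector(dropout),
    stringsAsFactors = FALSE)
  panel <- as_panel(rec, wave_years = yrs, instrument_range = rng)
  list(panel = panel,
       truth = list(config = config, alpha = alpha, prone = prone,
                    health_base = health_base,
                    entry = entry_ind, exit = exit_ind,
                    dropout = dropout))
}
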