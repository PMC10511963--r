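#' Default covariate specification for the shipped cohort layout
#'
#' Matches the adjustment set used in the late-life employment analyses:
#' age, age squared, sex, education, partnership, pre-1945 birth cohort and
#' (last-observed) occupation level at the treatment wave; self-reported
#' health, income tertile, asset tertile and the lagged cognitive score over
#' the lag window. Missing covariate values get the 0/indicator treatment.
#'
#' @return a [covariate_spec()].
#' @export
default_covariate_spec <- function() {
  covariate_spec(
    time_invariant = c("age", "age2", "female", "education", "spouse",
                       "birth1945", "occupation"),
    time_varying = c("health", "income", "asset", "outcome"),
    tertile_vars = c("income", "asset"),
    missing_indicator_vars = "auto",
    locf_vars = "occupation")
}

#' Matched difference-in-differences for one transition direction
#'
#' The full design in one call: codes entry or exit transitions inside the
#' treatment window, applies the consecutive-participation and minimum-age
#' eligibility filters, matches treated person-waves to controls with
#' identical employment histories over the lag window, refines the matched
#' sets on pre-treatment covariate histories, and estimates the
#' difference-in-differences contrast at each lead `F = 0..leads`, with
#' weighted block-bootstrap standard errors. Both the refined ("adjusted")
#' and equal-weight ("unadjusted") estimates are returned, plus covariate
#' balance and pre-trend diagnostics.
#'
#' @param panel a `cohort_panel`.
#' @param direction `"entry"` (non-employed to employed) or `"exit"`.
#' @param lags employment-history length L matched on (default 3 waves;
#'   use 2 for the sensitivity design).
#' @param leads largest lead F estimated (default 1).
#' @param window calendar-year range of treatable transitions.
#' @param refinement matched-set refinement method (see [fit_refinement()]).
#' @param covariates a [covariate_spec()]; default [default_covariate_spec()]
#'   restricted to columns present in the panel.
#' @param min_age minimum age at the transition wave (`NULL` disables).
#' @param size_match J for matching-type refinements.
#' @param bootstrap logical; compute block-bootstrap SE/CIs.
#' @param reps bootstrap replicates (reference design: 1000).
#' @param seed seed for the bootstrap resampling.
#' @param ci_mode `"percentile"` or `"normal"`.
#' @param diagnostics logical; compute balance and pre-trend tables.
#' @return object of class `panel_did` with elements `results` (data.frame:
#'   direction, F, adjusted, estimate, se, ci_low, ci_high, n_treated,
#'   n_unmatched), `balance`, `pretrend`, `exclusions`, `matched_sets`,
#'   `refinement_model`, `config`.
#' @export
panel_did <- function(panel, direction = c("entry", "exit"),
                      lags = 3L, leads = 1L, window = c(2012L, 2018L),
                      refinement = c("cbps_weight", "ps_weight", "ps_match",
                                     "mahalanobis", "none"),
                      covariates = NULL, min_age = 65,
                      size_match = 5L, bootstrap = TRUE, reps = 1000L,
                      seed = 1L, ci_mode = c("percentile", "normal"),
                      diagnostics = TRUE) {
  direction <- match.arg(direction)
  refinement <- match.arg(refinement)
  ci_mode <- match.arg(ci_mode)
  stopifnot(inherits(panel, "cohort_panel"), lags >= 1L, leads >= 0L)
  cl <- match.call()

  ev <- code_transitions(panel, direction, window = window)
  excl_code <- attr(ev, "exclusions")
  n_coded <- nrow(ev)
  ev <- apply_eligibility(panel, ev, lags = lags, leads = leads,
                          min_age = min_age)
  excl_elig <- attr(ev, "exclusions")
  if (nrow(ev) == 0L || !any(ev$treated)) {
    stop("no estimable events: no treated transitions survive eligibility")
  }

  if (is.null(covariates)) {
    spec <- default_covariate_spec()
    have <- names(panel$records)
    spec$time_invariant <- intersect(spec$time_invariant, have)
    spec$time_varying <- intersect(spec$time_varying, c(have, "outcome"))
    spec$tertile_vars <- intersect(spec$tertile_vars, spec$time_varying)
    spec$locf_vars <- intersect(spec$locf_vars, have)
    covariates <- spec
  }

  msets <- build_matched_sets(ev, panel, lags = lags)
  X <- build_covariates(panel, msets$events, covariates, lags = lags)
  model <- fit_refinement(msets, X, method = refinement,
                          size_match = size_match)
  refined <- refine(msets, X, model)

  rows <- list()
  for (F in 0:leads) {
    for (adj in c(FALSE, TRUE)) {
      r <- if (adj) estimate_did(refined, panel, F = F)
           else estimate_unadjusted(msets, panel, F = F)
      if (bootstrap) {
        r <- block_bootstrap(if (adj) refined else msets, panel, F = F,
                             reps = reps, seed = seed + F, ci_mode = ci_mode)
        attr(r, "replicates") <- NULL
      }
      rows[[length(rows) + 1L]] <- data.frame(
        direction = direction, F = F,
        adjusted = if (adj) "adjusted" else "unadjusted",
        estimate = r$estimate, se = r$se,
        ci_low = r$ci_low, ci_high = r$ci_high,
        n_treated = r$n_treated, n_unmatched = r$n_unmatched,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)

  bal <- pret <- NULL
  if (diagnostics) {
    bal <- balance_smd(refined, X)
    pret <- pretrend_check(refined, panel, lags = lags)
  }
  exclusions <- c(excl_code, excl_elig)
  structure(list(call = cl, results = results, balance = bal,
                 pretrend = pret, exclusions = exclusions,
                 n_events_coded = n_coded,
                 matched_sets = refined, unrefined_sets = msets,
                 refinement_model = model, covariate_matrix = X,
                 config = list(direction = direction, lags = lags,
                               leads = leads, window = window,
                               refinement = refinement, min_age = min_age,
                               size_match = size_match, reps = reps,
                               seed = seed, ci_mode = ci_mode)),
            class = "panel_did")
}

#' @export
print.panel_did <- function(x, digits = 3, ...) {
  cat("Matched difference-in-differences (", x$config$direction,
      ", L = ", x$config$lags, ", refinement = ", x$config$refinement,
      ")\n", sep = "")
  cat("Treated events:", x$results$n_treated[1] + x$results$n_unmatched[1],
      "matched:", x$results$n_treated[1],
      "unmatched:", x$results$n_unmatched[1], "\n\n")
  df <- x$results
  num <- c("estimate", "se", "ci_low", "ci_high")
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.panel_did <- function(object, ...) {
  out <- list(results = object$results,
              exclusions = object$exclusions,
              config = object$config)
  if (!is.null(object$balance)) {
    out$max_smd_before <- max(abs(object$balance$smd_before), na.rm = TRUE)
    out$max_smd_after <- max(abs(object$balance$smd_after), na.rm = TRUE)
    pre <- object$pretrend
    out$max_pretrend_smd <- max(abs(pre$smd_after[pre$type == "change"]),
                                0, na.rm = TRUE)
  }
  class(out) <- "summary.panel_did"
  out
}

#' @export
print.summary.panel_did <- function(x, digits = 3, ...) {
  cat("Matched DID summary (", x$config$direction, ")\n", sep = "")
  df <- x$results
  num <- c("estimate", "se", "ci_low", "ci_high")
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  cat("\nExclusions:\n")
  print(x$exclusions)
  if (!is.null(x$max_smd_before)) {
    cat(sprintf("\nCovariate balance: max |SMD| %.3f (before) -> %.3f (after)\n",
                x$max_smd_before, x$max_smd_after))
    cat(sprintf("Pre-trend: max |SMD| of pre-period outcome changes %.3f\n",
                x$max_pretrend_smd))
  }
  invisible(x)
}

#' @export
coef.panel_did <- function(object, adjusted = TRUE, ...) {
  df <- object$results
  df <- df[df$adjusted == if (adjusted) "adjusted" else "unadjusted", ]
  stats::setNames(df$estimate,
                  paste0(df$direction, ".F", df$F))
}

#' @export
confint.panel_did <- function(object, parm, level = 0.95,
                              adjusted = TRUE, ...) {
  if (level != 0.95) {
    stop("only the 95% interval computed by the bootstrap is stored")
  }
  df <- object$results
  df <- df[df$adjusted == if (adjusted) "adjusted" else "unadjusted", ]
  out <- cbind(`2.5 %` = df$ci_low, `97.5 %` = df$ci_high)
  rownames(out) <- paste0(df$direction, ".F", df$F)
  out
}

#' Point-range plot of the estimated effects by lead
#'
#' @param x a `panel_did` object.
#' @param adjusted plot the adjusted (default) or unadjusted estimates.
#' @param ... passed to [graphics::plot()].
#' @export
plot.panel_did <- function(x, adjusted = TRUE, ...) {
  df <- x$results
  df <- df[df$adjusted == if (adjusted) "adjusted" else "unadjusted", ]
  ylim <- range(c(df$ci_low, df$ci_high, 0), na.rm = TRUE)
  graphics::plot(df$F, df$estimate, pch = 19, xaxt = "n",
                 xlab = "Lead (waves after transition)",
                 ylab = "DID estimate (score points)",
                 ylim = ylim,
                 main = paste0("Effect of labour-market ",
                               x$config$direction,
                               if (adjusted) " (adjusted)" else
                                 " (unadjusted)"), ...)
  graphics::axis(1, at = df$F)
  if (!all(is.na(df$ci_low))) {
    graphics::arrows(df$F, df$ci_low, df$F, df$ci_high,
                     angle = 90, code = 3, length = 0.05)
  }
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
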