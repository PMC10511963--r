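#' Run the full study design end to end
#'
#' Executes cohort preparation, matching, refinement, estimation, inference
#' and diagnostics for both transition directions, writing delimited text
#' outputs in the shape of the reference analysis: one results table with
#' 2 directions x {unadjusted, adjusted} x leads rows, one balance table and
#' one exclusion tally per direction, a run log, and optional subgroup
#' results files. Subgroup analyses re-run the entire matching and
#' refinement within the subgroup, so matched controls share subgroup
#' membership.
#'
#' @param panel a `cohort_panel`, or `NULL` to generate one from `scenario`.
#' @param scenario a [scenario_config()] used when `panel` is `NULL`.
#' @param out_dir output directory (created if missing); `NULL` writes
#'   nothing and only returns the results.
#' @param directions subset of `c("entry", "exit")`.
#' @param subgroups character subset of `c("asset", "education", "sex")`:
#'   median split on baseline asset, education up to high school vs above
#'   (codes <= 3 vs 4), and sex. Each subgroup analysis is written to its
#'   own results file; inestimable cells are reported as `NA` with a reason
#'   and the run continues.
#' @param lags,leads,window,refinement,min_age,size_match,reps,seed,ci_mode
#'   passed to [panel_did()].
#' @param bootstrap logical; bootstrap SEs in the main run.
#' @return (invisibly) list with `results`, `balance`, `pretrend`,
#'   `exclusions`, `subgroups`, `files`, `fits`.
#' @export
run_study <- function(panel = NULL, scenario = NULL, out_dir = NULL,
                      directions = c("entry", "exit"),
                      subgroups = character(),
                      lags = 3L, leads = 1L, window = c(2012L, 2018L),
                      refinement = "cbps_weight", min_age = 65,
                      size_match = 5L, bootstrap = TRUE, reps = 1000L,
                      seed = 1L, ci_mode = "percentile") {
  if (is.null(panel)) {
    if (is.null(scenario)) stop("supply a panel or a scenario_config")
    panel <- generate_cohort(scenario)$panel
  }
  directions <- match.arg(directions, c("entry", "exit"),
                          several.ok = TRUE)
  tag <- paste0("lag", lags)
  log_lines <- c(
    paste0("# matchdid run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", seed),
    paste0("config: lags=", lags, " leads=", leads,
           " window=", window[1], "-", window[2],
           " refinement=", refinement, " min_age=", min_age,
           " reps=", if (bootstrap) reps else 0, " ci=", ci_mode),
    paste0("units: ", length(panel_units(panel)),
           " records: ", nrow(panel$records)))

  fits <- list(); res <- list(); bal <- list(); pret <- list()
  excl <- list()
  for (d in directions) {
    fit <- panel_did(panel, d, lags = lags, leads = leads, window = window,
                     refinement = refinement, min_age = min_age,
                     size_match = size_match, bootstrap = bootstrap,
                     reps = reps, seed = seed, ci_mode = ci_mode)
    fits[[d]] <- fit
    res[[d]] <- fit$results
    bal[[d]] <- fit$balance
    pret[[d]] <- fit$pretrend
    excl[[d]] <- data.frame(direction = d,
                            criterion = names(fit$exclusions),
                            n_excluded = as.integer(fit$exclusions),
                            stringsAsFactors = FALSE)
    log_lines <- c(log_lines,
                   paste0(d, ": coded=", fit$n_events_coded,
                          " treated_matched=", fit$results$n_treated[1],
                          " unmatched=", fit$results$n_unmatched[1]))
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  exclusions <- do.call(rbind, excl)
  rownames(exclusions) <- NULL

  sub_res <- list()
  for (sg in subgroups) {
    sub_res[[sg]] <- run_subgroup(panel, sg, directions, lags, leads,
                                  window, refinement, min_age, size_match,
                                  bootstrap, reps, seed, ci_mode)
  }

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_res <- file.path(out_dir, paste0("results_", tag, ".csv"))
    utils::write.csv(results, f_res, row.names = FALSE)
    files <- f_res
    for (d in directions) {
      f_bal <- file.path(out_dir,
                         paste0("balance_", d, "_", refinement, "_",
                                tag, ".csv"))
      utils::write.csv(as.data.frame(bal[[d]]), f_bal, row.names = FALSE)
      files <- c(files, f_bal)
    }
    f_ex <- file.path(out_dir, paste0("exclusions_", tag, ".csv"))
    utils::write.csv(exclusions, f_ex, row.names = FALSE)
    files <- c(files, f_ex)
    for (sg in names(sub_res)) {
      f_sg <- file.path(out_dir,
                        paste0("results_subgroup_", sg, "_", tag, ".csv"))
      utils::write.csv(sub_res[[sg]], f_sg, row.names = FALSE)
      files <- c(files, f_sg)
    }
    f_log <- file.path(out_dir, paste0("run_", tag, ".log"))
    writeLines(log_lines, f_log)
    files <- c(files, f_log)
  }
  invisible(list(results = results, balance = bal, pretrend = pret,
                 exclusions = exclusions, subgroups = sub_res,
                 files = files, fits = fits, log = log_lines))
}

# Internal: one subgroup analysis = full pipeline re-run inside the subgroup.
run_subgroup <- function(panel, sg, directions, lags, leads, window,
                         refinement, min_age, size_match, bootstrap, reps,
                         seed, ci_mode) {
  rec <- panel$records
  first_wave <- stats::aggregate(wave_index ~ unit_id,
                                 data = rec[rec$observed, ], FUN = min)
  base <- merge(first_wave, rec,
                by = c("unit_id", "wave_index"), all.x = TRUE)
  split_def <- switch(sg,
    asset = {
      if (!"asset" %in% names(rec)) stop("panel has no 'asset' column")
      med <- stats::median(base$asset, na.rm = TRUE)
      list(lo = base$unit_id[!is.na(base$asset) & base$asset <= med],
           hi = base$unit_id[!is.na(base$asset) & base$asset > med],
           labels = c("below_median_asset", "above_median_asset"))
    },
    education = {
      if (!"education" %in% names(rec)) stop("panel has no 'education'")
      list(lo = base$unit_id[!is.na(base$education) & base$education <= 3],
           hi = base$unit_id[!is.na(base$education) & base$education > 3],
           labels = c("upto_high_school", "above_high_school"))
    },
    sex = {
      if (!"female" %in% names(rec)) stop("panel has no 'female' column")
      list(lo = base$unit_id[!is.na(base$female) & base$female == 1],
           hi = base$unit_id[!is.na(base$female) & base$female == 0],
           labels = c("female", "male"))
    },
    stop("unknown subgroup: ", sg))
  out <- list()
  for (half in c("lo", "hi")) {
    lab <- split_def$labels[match(half, c("lo", "hi"))]
    sub_rec <- rec[rec$unit_id %in% split_def[[half]], , drop = FALSE]
    for (d in directions) {
      row <- tryCatch({
        sub_panel <- as_panel(sub_rec, wave_years = panel$wave_years,
                              instrument_range = panel$instrument_range)
        fit <- panel_did(sub_panel, d, lags = lags, leads = leads,
                         window = window, refinement = refinement,
                         min_age = min_age, size_match = size_match,
                         bootstrap = bootstrap, reps = reps, seed = seed,
                         ci_mode = ci_mode, diagnostics = FALSE)
        cbind(subgroup = lab, fit$results, reason = "",
              stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(subgroup = lab, direction = d, F = NA_integer_,
                   adjusted = NA_character_, estimate = NA_real_,
                   se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   n_treated = NA_integer_, n_unmatched = NA_integer_,
                   reason = conditionMessage(e), stringsAsFactors = FALSE)
      })
      out[[paste(lab, d)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte-Carlo evaluation of the full design on a synthetic scenario
#'
#' Repeats generate-and-analyse `n_sims` times and aggregates estimate bias
#' against the scenario's true effects, the empirical SE of the estimator,
#' the mean bootstrap SE, and 95% CI coverage, per (direction, lead,
#' adjustment) cell. Truth at F = 0 is the scenario's tau; truth at F = 1 is
#' its carry-over (signed per direction).
#'
#' @param scenario a [scenario_config()]; its `seed` is overridden per
#'   simulation by `seed + sim`.
#' @param n_sims number of simulated cohorts (>= 2).
#' @param seed master seed.
#' @param directions subset of `c("entry", "exit")`.
#' @param bootstrap logical; if `TRUE` compute bootstrap CIs and coverage.
#' @param reps bootstrap replicates per simulation.
#' @param lags,leads,refinement,min_age passed to [panel_did()].
#' @return list with `cells` (summary data.frame: direction, F, adjusted,
#'   truth, mean_estimate, bias, empirical_se, mean_boot_se, rmse,
#'   coverage) and `draws` (per-sim estimates).
#' @export
simulate_study <- function(scenario, n_sims = 100L, seed = 1L,
                           directions = "entry", bootstrap = FALSE,
                           reps = 500L, lags = 3L, leads = 1L,
                           refinement = "cbps_weight", min_age = 65) {
  if (n_sims < 2L) stop("n_sims must be at least 2")
  draws <- list()
  for (sim in seq_len(n_sims)) {
    sc <- scenario
    sc$seed <- seed + sim
    panel <- generate_cohort(sc)$panel
    for (d in directions) {
      fit <- tryCatch(
        panel_did(panel, d, lags = lags, leads = leads,
                  refinement = refinement, min_age = min_age,
                  bootstrap = bootstrap, reps = reps, seed = seed + sim,
                  diagnostics = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) next
      draws[[length(draws) + 1L]] <- cbind(sim = sim, fit$results)
    }
  }
  draws <- do.call(rbind, draws)
  truth_at <- function(d, F) {
    tau <- if (d == "entry") scenario$tau_entry else scenario$tau_exit
    co <- if (d == "entry") scenario$carryover_f1 else -scenario$carryover_f1
    if (F == 0) tau else co
  }
  key <- interaction(draws$direction, draws$F, draws$adjusted, drop = TRUE)
  cells <- lapply(split(draws, key), function(g) {
    tr <- truth_at(g$direction[1], g$F[1])
    data.frame(direction = g$direction[1], F = g$F[1],
               adjusted = g$adjusted[1], truth = tr,
               n_sims = nrow(g),
               mean_estimate = mean(g$estimate),
               bias = mean(g$estimate) - tr,
               empirical_se = stats::sd(g$estimate),
               mean_boot_se = mean(g$se),
               rmse = sqrt(mean((g$estimate - tr)^2)),
               coverage = if (all(is.na(g$ci_low))) NA_real_
                          else mean(g$ci_low <= tr & tr <= g$ci_high),
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  list(cells = cells, draws = draws)
}
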