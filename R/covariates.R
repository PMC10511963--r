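#' Declare the covariates used for matched-set refinement
#'
#' Time-invariant covariates are measured at the treatment wave `t`;
#' time-varying covariates are measured at each of the lag waves
#' `t - 1 .. t - L`, capturing the pre-treatment trajectory. The reserved
#' name `"outcome"` in `time_varying` includes the lagged cognitive score
#' itself among the matched covariates.
#'
#' @param time_invariant character vector of column names measured at `t`.
#' @param time_varying character vector of column names measured at the lag
#'   waves (may include `"outcome"`).
#' @param tertile_vars names replaced by within-wave tertile ranks (1/2/3),
#'   the usual treatment of household income and asset as relative economic
#'   status.
#' @param missing_indicator_vars names given the dummy-adjustment treatment
#'   (missing value set to 0 plus a 0/1 observed indicator); the default
#'   `"auto"` applies it to every variable with any missing extracted value.
#' @param locf_vars names filled by last observation carried forward before
#'   measurement (used for high-missingness variables such as occupation).
#' @param reference_levels named list giving the reference level for
#'   categorical (character/factor) variables; default is the first sorted
#'   level.
#' @return object of class `covariate_spec`.
#' @export
covariate_spec <- function(time_invariant = character(),
                           time_varying = character(),
                           tertile_vars = intersect(
                             c("income", "asset"),
                             c(time_invariant, time_varying)),
                           missing_indicator_vars = "auto",
                           locf_vars = character(),
                           reference_levels = list()) {
  both <- intersect(time_invariant, time_varying)
  if (length(both)) {
    stop("covariate(s) in both invariant and varying lists: ",
         paste(both, collapse = ", "))
  }
  all_vars <- c(time_invariant, time_varying)
  extra <- setdiff(tertile_vars, all_vars)
  if (length(extra)) {
    stop("tertile_vars not among declared covariates: ",
         paste(extra, collapse = ", "))
  }
  structure(list(time_invariant = time_invariant,
                 time_varying = time_varying,
                 tertile_vars = tertile_vars,
                 missing_indicator_vars = missing_indicator_vars,
                 locf_vars = locf_vars,
                 reference_levels = reference_levels),
            class = "covariate_spec")
}

# Internal: within-wave tertile rank of a units x waves value matrix.
# Cut points are the 1/3 and 2/3 quantiles of the non-missing values in each
# wave column, computed over the supplied row subset (the event-eligible
# sample); the rank map is invariant to strictly monotone transforms.
tertile_rank_matrix <- function(m, rows = seq_len(nrow(m))) {
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[rows, j]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    qs <- stats::quantile(v, c(1 / 3, 2 / 3), names = FALSE, na.rm = TRUE)
    out[, j] <- 1 + (m[, j] > qs[1]) + (m[, j] > qs[2])
  }
  out
}

# Internal: last observation carried forward along waves.
locf_matrix <- function(m) {
  if (ncol(m) < 2L) return(m)
  for (j in 2:ncol(m)) {
    na <- is.na(m[, j])
    m[na, j] <- m[na, j - 1L]
  }
  m
}

#' Build the flattened covariate-history matrix for a set of events
#'
#' One row per event: time-invariant covariates at the transition wave `t`,
#' time-varying covariates at each lag wave `t - 1 .. t - lags`. Tertile
#' variables are replaced by their within-wave tertile rank computed over
#' the event sample; categorical variables are one-hot encoded against a
#' reference level; variables with missing values contribute a 0-imputed
#' value column plus a 0/1 observed indicator.
#'
#' @param panel a `cohort_panel`.
#' @param events event data.frame (typically after [apply_eligibility()]).
#' @param spec a [covariate_spec()].
#' @param lags number of lag waves L for the time-varying block.
#' @return numeric matrix (rows = events) with attribute `feature_info`, a
#'   data.frame mapping each column to its source variable, lag (`NA` for
#'   time-invariant) and type (`"value"` or `"indicator"`).
#' @export
build_covariates <- function(panel, events, spec, lags = 3L) {
  stopifnot(inherits(panel, "cohort_panel"),
            inherits(spec, "covariate_spec"), lags >= 1L)
  rec <- panel$records
  vars <- c(spec$time_invariant, spec$time_varying)
  known <- setdiff(vars, "outcome")
  absent <- setdiff(known, names(rec))
  if (length(absent)) {
    stop("covariate(s) not in panel: ", paste(absent, collapse = ", "))
  }
  units <- panel_units(panel)
  iu <- match(events$unit_id, units)
  sample_rows <- sort(unique(iu))

  val_matrix <- function(v) {
    if (v == "outcome") {
      m <- panel_matrix(panel, "outcome")
    } else if (is.numeric(rec[[v]]) || is.logical(rec[[v]])) {
      m <- panel_matrix(panel, v, respect_observed = FALSE)
    } else {
      return(NULL)  # categorical: handled separately
    }
    if (v %in% spec$locf_vars) m <- locf_matrix(m)
    if (v %in% spec$tertile_vars) m <- tertile_rank_matrix(m, sample_rows)
    m
  }
  chr_matrix <- function(v) {
    m <- matrix(NA_character_, nrow = length(units),
                ncol = length(panel$wave_years))
    m[cbind(match(rec$unit_id, units), rec$wave_index + 1L)] <-
      as.character(rec[[v]])
    if (v %in% spec$locf_vars) {
      for (j in 2:ncol(m)) {
        na <- is.na(m[, j]); m[na, j] <- m[na, j - 1L]
      }
    }
    m
  }

  cols <- list(); info <- list()
  add_slot <- function(values, var, lag, label) {
    # expand one extracted slot (numeric or character) into columns
    if (is.character(values)) {
      lev <- sort(unique(values[!is.na(values)]))
      ref <- spec$reference_levels[[var]]
      if (is.null(ref)) ref <- lev[1L]
      lev <- setdiff(lev, ref)
      for (lv in lev) {
        cols[[paste0(label, ".", lv)]] <<- as.numeric(values == lv)
        info[[length(info) + 1L]] <<- data.frame(
          feature = paste0(label, ".", lv), var = var, lag = lag,
          type = "value", stringsAsFactors = FALSE)
      }
    } else {
      cols[[label]] <<- values
      info[[length(info) + 1L]] <<- data.frame(
        feature = label, var = var, lag = lag, type = "value",
        stringsAsFactors = FALSE)
    }
  }

  for (v in spec$time_invariant) {
    if (is.numeric(rec[[v]]) || is.logical(rec[[v]])) {
      m <- val_matrix(v)
      add_slot(m[cbind(iu, events$t + 1L)], v, NA_integer_, v)
    } else {
      m <- chr_matrix(v)
      add_slot(m[cbind(iu, events$t + 1L)], v, NA_integer_, v)
    }
  }
  for (v in spec$time_varying) {
    is_cat <- v != "outcome" && !(is.numeric(rec[[v]]) || is.logical(rec[[v]]))
    m <- if (is_cat) chr_matrix(v) else val_matrix(v)
    for (k in seq_len(lags)) {
      add_slot(m[cbind(iu, events$t - k + 1L)], v, k,
               paste0(v, ".l", k))
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  info <- do.call(rbind, info)

  # all-missing check per source variable
  for (v in vars) {
    idx <- which(info$var == v)
    if (length(idx) && all(is.na(X[, idx]))) {
      stop("covariate '", v, "' is missing for every event")
    }
  }

  # dummy adjustment for partially observed variables
  miv <- spec$missing_indicator_vars
  if (identical(miv, "auto")) {
    miv <- unique(info$var[colSums(is.na(X[, info$feature, drop = FALSE])) > 0])
  }
  new_cols <- list(); new_info <- list()
  for (j in seq_len(ncol(X))) {
    f <- info[j, ]
    col <- X[, j]
    new_cols[[f$feature]] <- col
    new_info[[length(new_info) + 1L]] <- f
    if (f$var %in% miv) {
      ind <- as.numeric(!is.na(col))
      new_cols[[f$feature]][is.na(col)] <- 0
      lab <- paste0(f$feature, ".obs")
      new_cols[[lab]] <- ind
      new_info[[length(new_info) + 1L]] <- data.frame(
        feature = lab, var = f$var, lag = f$lag, type = "indicator",
        stringsAsFactors = FALSE)
    } else if (anyNA(col)) {
      # shouldn't happen under "auto"; be explicit rather than silent
      stop("covariate '", f$var,
           "' has missing values but no missing indicator declared")
    }
  }
  X <- do.call(cbind, new_cols)
  colnames(X) <- names(new_cols)
  rownames(X) <- NULL
  info <- do.call(rbind, new_info)
  rownames(info) <- NULL
  attr(X, "feature_info") <- info
  X
}
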