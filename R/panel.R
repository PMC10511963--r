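#' Construct a longitudinal cohort panel
#'
#' A `cohort_panel` holds one row per person-wave of a long-format panel:
#' a unit identifier, calendar year, binary employment status, a bounded
#' integer cognitive score, and any number of covariate columns. Waves are
#' indexed by position in `wave_years` (0-based), so the machinery is
#' agnostic to the calendar spacing; the default design is the biennial
#' 2006--2020 survey layout.
#'
#' Missingness is first-class: `employed` and `outcome` may be `NA`, and a
#' record counts as observed only when its employment status is non-missing
#' (an `observed` column, if supplied, overrides this rule).
#'
#' @param records data.frame with at least columns `unit_id`, `year`,
#'   `employed`, `outcome`; additional columns are kept as covariates.
#' @param wave_years strictly increasing integer vector of survey years.
#'   Defaults to the sorted unique years present in `records`.
#' @param instrument_range length-2 numeric; admissible outcome range.
#'   Use `c(0, 30)` for MMSE-like and `c(0, 27)` for TICS-like scores.
#' @return object of class `cohort_panel`: a list with `records` (the
#'   validated data.frame, with an integer `wave_index` column added),
#'   `wave_years` and `instrument_range`.
#' @export
as_panel <- function(records, wave_years = NULL,
                     instrument_range = c(0, 30)) {
  stopifnot(is.data.frame(records))
  needed <- c("unit_id", "year", "employed", "outcome")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) {
    stop("panel records lack required column(s): ",
         paste(miss, collapse = ", "))
  }
  records$unit_id <- as.character(records$unit_id)
  records$year <- as.integer(records$year)
  if (is.null(wave_years)) wave_years <- sort(unique(records$year))
  wave_years <- as.integer(wave_years)
  if (any(diff(wave_years) <= 0L)) stop("wave_years must be strictly increasing")
  bad_year <- !(records$year %in% wave_years)
  if (any(bad_year)) {
    stop(sum(bad_year), " record(s) with year outside wave_years (first: year ",
         records$year[which(bad_year)[1L]], ")")
  }
  if (!is.numeric(records$outcome) && !all(is.na(records$outcome))) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$outcome))) &
                   !is.na(records$outcome) & records$outcome != "")
    stop("non-numeric outcome value at row ",
         if (length(bad)) bad[1L] else NA)
  }
  records$outcome <- suppressWarnings(as.numeric(records$outcome))
  records$employed <- suppressWarnings(as.numeric(records$employed))
  ok_emp <- is.na(records$employed) | records$employed %in% c(0, 1)
  if (!all(ok_emp)) {
    stop("employed must be 0, 1 or missing (row ", which(!ok_emp)[1L], ")")
  }
  out_rng <- range(records$outcome, na.rm = TRUE)
  if (any(!is.na(records$outcome)) &&
      (out_rng[1] < instrument_range[1] || out_rng[2] > instrument_range[2])) {
    bad <- which(!is.na(records$outcome) &
                   (records$outcome < instrument_range[1] |
                      records$outcome > instrument_range[2]))[1L]
    stop("outcome ", records$outcome[bad], " outside instrument range [",
         instrument_range[1], ", ", instrument_range[2], "] (unit ",
         records$unit_id[bad], ", year ", records$year[bad], ")")
  }
  records$wave_index <- match(records$year, wave_years) - 1L
  key <- paste(records$unit_id, records$wave_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate record for (unit ", d$unit_id, ", year ", d$year, ")")
  }
  if (!"observed" %in% names(records)) {
    records$observed <- !is.na(records$employed)
  } else {
    records$observed <- as.logical(records$observed)
  }
  records <- records[order(records$unit_id, records$wave_index), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 wave_years = wave_years,
                 instrument_range = as.numeric(instrument_range)),
            class = "cohort_panel")
}

#' Read a panel from a delimited text file
#'
#' @param path CSV file (header row, UTF-8).
#' @param schema named list/character mapping the canonical names
#'   (`unit_id`, `year`, `employed`, `outcome`) to the column names used in
#'   the file; columns not mentioned are carried through as covariates.
#' @param wave_years survey years to keep; rows with other years are dropped
#'   (the count is reported in attribute `n_rejected`). `NULL` keeps all.
#' @inheritParams as_panel
#' @return a `cohort_panel`; attribute `n_rejected` counts dropped rows.
#' @export
read_panel <- function(path, schema = NULL, wave_years = NULL,
                       instrument_range = c(0, 30)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) stop("schema column not in file: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"year" %in% names(df)) stop("no 'year' column after schema mapping")
  n_rej <- 0L
  if (!is.null(wave_years)) {
    keep <- df$year %in% wave_years
    n_rej <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  if ("outcome" %in% names(df) && is.character(df$outcome)) {
    num <- suppressWarnings(as.numeric(df$outcome))
    bad <- which(is.na(num) & !is.na(df$outcome) & df$outcome != "")
    if (length(bad)) stop("non-numeric outcome at data row ", bad[1L],
                          " ('", df$outcome[bad[1L]], "')")
    df$outcome <- num
  }
  p <- as_panel(df, wave_years = wave_years,
                instrument_range = instrument_range)
  attr(p, "n_rejected") <- n_rej
  p
}

#' Write a panel back to CSV
#'
#' Inverse of [read_panel()]: cell values round-trip (up to column order).
#' The derived `wave_index` column is not written.
#'
#' @param panel a `cohort_panel`.
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "cohort_panel"))
  rec <- panel$records
  rec$wave_index <- NULL
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Look up a lagged field value for one unit
#'
#' @param panel a `cohort_panel`.
#' @param unit unit identifier.
#' @param t wave index (0-based).
#' @param k non-negative lag; `k = 0` returns the wave-`t` value.
#' @param field column name in the panel records.
#' @return the value at wave `t - k`, or `NA` if that person-wave is absent
#'   or unobserved.
#' @export
get_lagged <- function(panel, unit, t, k, field) {
  stopifnot(inherits(panel, "cohort_panel"), k >= 0)
  if (k > t) stop("lag k = ", k, " exceeds wave index t = ", t,
                  " (out of window)")
  rec <- panel$records
  i <- which(rec$unit_id == as.character(unit) & rec$wave_index == t - k)
  if (length(i) == 0L) return(NA)
  if (!isTRUE(rec$observed[i])) return(NA)
  rec[[field]][i]
}

#' @export
print.cohort_panel <- function(x, ...) {
  rec <- x$records
  cat("cohort_panel:", length(unique(rec$unit_id)), "units,",
      length(x$wave_years), "waves (",
      paste(range(x$wave_years), collapse = "-"), "),",
      nrow(rec), "person-wave records\n")
  cat("  outcome range [", x$instrument_range[1], ",",
      x$instrument_range[2], "]; observed records:",
      sum(rec$observed), "\n")
  covs <- setdiff(names(rec), c("unit_id", "year", "wave_index",
                                "employed", "outcome", "observed"))
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

# Internal: units x waves matrix of one field (fast path used throughout).
# Rows follow sort(unique(unit_id)); unobserved person-waves are NA.
panel_matrix <- function(panel, field, respect_observed = TRUE) {
  rec <- panel$records
  units <- sort(unique(rec$unit_id))
  W <- length(panel$wave_years)
  m <- matrix(NA_real_, nrow = length(units), ncol = W,
              dimnames = list(units, panel$wave_years))
  v <- rec[[field]]
  if (respect_observed) v[!rec$observed] <- NA
  m[cbind(match(rec$unit_id, units), rec$wave_index + 1L)] <- as.numeric(v)
  m
}

panel_units <- function(panel) sort(unique(panel$records$unit_id))
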