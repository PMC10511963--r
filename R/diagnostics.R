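#' Covariate balance table (standardised mean differences)
#'
#' For every covariate-history feature, the SMD is the treated mean minus
#' the matched-control mean (averaged over treated events with the set
#' weights), divided by the standard deviation among treated events — the
#' conventional matching diagnostic. Computed twice: before refinement
#' (equal weights within each set) and after (current weights).
#'
#' @param msets a refined `matched_sets` object.
#' @param X covariate matrix from [build_covariates()] aligned with
#'   `msets$events`.
#' @return data.frame of class `balance_table` with columns `feature`,
#'   `var`, `lag`, `smd_before`, `smd_after`. A zero treated SD yields SMD 0
#'   when the means agree and `NaN` (flagged undefined) otherwise.
#' @export
balance_smd <- function(msets, X) {
  stopifnot(inherits(msets, "matched_sets"))
  info <- attr(X, "feature_info")
  matched <- msets$sets[vapply(msets$sets, function(s)
    length(s$members) > 0L, logical(1))]
  if (length(matched) == 0L) stop("no matched treated events to diagnose")
  t_rows <- vapply(matched, `[[`, integer(1), "event_row")
  Xt <- X[t_rows, , drop = FALSE]
  mt <- colMeans(Xt)
  sdt <- apply(Xt, 2, stats::sd)

  ctrl_mean <- function(weighted) {
    acc <- matrix(0, length(matched), ncol(X))
    for (i in seq_along(matched)) {
      s <- matched[[i]]
      w <- if (weighted) s$weights
           else rep(1 / length(s$members), length(s$members))
      acc[i, ] <- drop(w %*% X[s$members, , drop = FALSE])
    }
    colMeans(acc)
  }
  mc_before <- ctrl_mean(FALSE)
  mc_after <- ctrl_mean(TRUE)
  smd <- function(mc) {
    d <- mt - mc
    out <- d / sdt
    zero_sd <- sdt == 0
    out[zero_sd & abs(d) < 1e-12] <- 0
    out[zero_sd & abs(d) >= 1e-12] <- NA_real_  # undefined, flagged as NA
    out
  }
  out <- data.frame(feature = colnames(X),
                    var = if (!is.null(info)) info$var else colnames(X),
                    lag = if (!is.null(info)) info$lag else NA_integer_,
                    smd_before = smd(mc_before),
                    smd_after = smd(mc_after),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Pre-treatment outcome trend check
#'
#' Tabular stand-in for a visual parallel-trend inspection: SMDs of the
#' lagged outcome *levels* at waves `t - 1 .. t - L` and of the lag-to-lag
#' outcome *changes* within the pre-treatment window, before and after
#' refinement. Under parallel trends the change SMDs should sit near zero
#' once covariates are balanced.
#'
#' @param msets a refined `matched_sets` object.
#' @param panel the `cohort_panel`.
#' @param lags pre-treatment window length L (defaults to the matching L).
#' @return `balance_table` with rows `outcome.l1 .. outcome.lL` (levels) and
#'   `d.outcome.l{k+1}.l{k}` (changes, absent when `L = 1`).
#' @export
pretrend_check <- function(msets, panel, lags = msets$lags) {
  Y <- panel_matrix(panel, "outcome")
  ev <- msets$events
  iu <- match(ev$unit_id, rownames(Y))
  cols <- list(); info <- list()
  for (k in seq_len(lags)) {
    cols[[paste0("outcome.l", k)]] <- Y[cbind(iu, ev$t - k + 1L)]
    info[[length(info) + 1L]] <- data.frame(
      feature = paste0("outcome.l", k), var = "outcome", lag = k,
      type = "level", stringsAsFactors = FALSE)
  }
  if (lags >= 2L) {
    for (k in seq_len(lags - 1L)) {
      lab <- paste0("d.outcome.l", k + 1L, ".l", k)
      cols[[lab]] <- Y[cbind(iu, ev$t - k + 1L)] -
        Y[cbind(iu, ev$t - k)]
      info[[length(info) + 1L]] <- data.frame(
        feature = lab, var = "outcome", lag = k, type = "change",
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(cbind, cols)
  attr(X, "feature_info") <- do.call(rbind, info)
  tb <- balance_smd(msets, X)
  tb$type <- attr(X, "feature_info")$type
  tb
}

#' @export
print.balance_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$smd_before <- round(df$smd_before, digits)
  df$smd_after <- round(df$smd_after, digits)
  print.data.frame(df)
  cat(sprintf("max |SMD|: before %.3f, after %.3f\n",
              max(abs(x$smd_before), na.rm = TRUE),
              max(abs(x$smd_after), na.rm = TRUE)))
  invisible(x)
}
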