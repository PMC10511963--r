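#' Tiny deterministic panels with hand-checkable matched sets
#'
#' Named fixtures used throughout the test suite; each is small enough
#' (<= 12 units, <= 6 waves) to verify matched sets by hand. All fixtures
#' carry an `age` column fixed at 66+ so the default eligibility age filter
#' keeps every event, and complete outcomes so the consecutive-participation
#' filter is inert unless a fixture says otherwise.
#'
#' Available fixtures:
#' \describe{
#'   \item{`histories8`}{8 units realising all 8 length-3 employment
#'     histories over waves 1..3, plus duplicated control histories, so every
#'     combination of origin state and history occurs at wave 4.}
#'   \item{`unmatched`}{exactly one treated entry event whose history is
#'     shared by no control.}
#'   \item{`tie`}{one treated entry event with two controls at identical
#'     covariate distance, so nearest-1 selection must tie-break by unit id.}
#'   \item{`reuse`}{one control unit serving in the matched sets of two
#'     different treated events.}
#' }
#'
#' @param name fixture name.
#' @return a `cohort_panel`.
#' @export
make_fixture <- function(name = c("histories8", "unmatched", "tie",
                                  "reuse")) {
  name <- match.arg(name)
  yrs <- seq(2006L, 2016L, by = 2L)  # 6 waves, indices 0..5
  mk <- function(emp_rows, out_rows = NULL, extra = NULL) {
    n <- length(emp_rows)
    ids <- sprintf("f%02d", seq_len(n))
    W <- length(yrs)
    if (is.null(out_rows)) {
      out_rows <- lapply(seq_len(n), function(i) 20 + seq_len(W) %% 3 + i %% 4)
    }
    rec <- data.frame(
      unit_id = rep(ids, each = W),
      year = rep(yrs, n),
      employed = unlist(emp_rows),
      outcome = unlist(out_rows),
      age = rep(66 + 2 * (seq_len(W) - 1L), n),
      stringsAsFactors = FALSE)
    if (!is.null(extra)) for (nm in names(extra)) {
      rec[[nm]] <- unlist(lapply(extra[[nm]], function(v)
        if (length(v) == 1L) rep(v, W) else v))
    }
    as_panel(rec, wave_years = yrs)
  }
  switch(name,
    histories8 = {
      # waves 1..3 realise all 8 histories; wave 4 (index 4, year 2014)
      # extends each by 0 and 1 via two units per history where useful.
      h <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
      emp <- lapply(seq_len(8), function(i) {
        c(0, h$a[i], h$b[i], h$c[i], ifelse(i %% 2 == 1, 1, 0), 0)
      })
      # add 4 more controls replicating histories (0,0,0)->0 and (1,1,1)->1
      emp <- c(emp,
               list(c(0, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 0),
                    c(0, 1, 1, 1, 1, 1), c(0, 1, 1, 1, 1, 1)))
      mk(emp)
    },
    unmatched = {
      # treated entry at wave 4 with history (1,0,0) shared by no control
      emp <- list(c(0, 1, 0, 0, 1, 0),   # treated: history 1,0,0 -> enters
                  c(0, 0, 0, 0, 0, 0),   # control with history 0,0,0
                  c(0, 0, 0, 0, 0, 0),
                  c(1, 1, 1, 1, 1, 1))   # employed throughout (wrong origin)
      mk(emp)
    },
    tie = {
      # one treated entry at wave 4, two controls with covariate values
      # symmetric about the treated unit's (equal distance)
      emp <- list(c(0, 0, 0, 0, 1, 1),
                  c(0, 0, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 0, 0))
      mk(emp, extra = list(health = list(3, 2, 4), income = list(10, 8, 12),
                           asset = list(50, 40, 60)))
    },
    reuse = {
      # two treated entry events (waves 3 and 4); unit f03 is an eligible
      # control at both waves with matching histories
      emp <- list(c(0, 0, 0, 1, 1, 1),   # treated at wave 3
                  c(0, 0, 0, 0, 1, 1),   # treated at wave 4
                  c(0, 0, 0, 0, 0, 0))   # control both times
      mk(emp)
    })
}
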