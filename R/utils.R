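#' Label spawn dates with a season year
#'
#' Spawning at the study hatcheries runs from roughly December through
#' February, so a "spawn year" is a season that straddles a calendar-year
#' boundary. Dates from `boundary` (month-day, default July 1) of year `y`
#' through the day before the boundary of year `y + 1` are labeled season
#' `y + 1`, i.e. the calendar year containing the season's January.
#'
#' @param dates a `Date` vector.
#' @param boundary season boundary as `"mm-dd"`; dates on or after the
#'   boundary belong to the following season label.
#' @return integer vector of season labels.
#' @export
spawn_season <- function(dates, boundary = "07-01") {
  stopifnot(inherits(dates, "Date"))
  y <- as.integer(format(dates, "%Y"))
  md <- format(dates, "%m-%d")
  ifelse(md >= boundary, y + 1L, y)
}

#' Derive a stream of child seeds from one master seed
#'
#' All stochastic stages take their own seed so that any stage can be re-run
#' in isolation and reproduce its output. Child seeds are a deterministic
#' function of the master seed and a label, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the consumer.
#' @return a single integer seed.
#' @export
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# counts -> "n (xx.x%)" strings used by the table writers
fmt_count_pct <- function(n, denom) {
  pct <- ifelse(denom > 0, 100 * n / denom, NA_real_)
  sprintf("%d (%.1f%%)", n, pct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
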