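#' Observation window
#'
#' A closed calendar interval over which adherence and outcomes are computed.
#' Lengths are whole days, end date inclusive; calendar year 2016 spans 366
#' days.
#'
#' @param start,end Window start and end dates (`Date` or ISO-8601 strings).
#' @return An object of class `observation_window` with fields `start`, `end`
#'   and `length_days`.
#' @examples
#' \dontrun{
#' observation_window("2016-01-01", "2016-12-31")$length_days  # 366
#' }
#' @export
observation_window <- function(start, end) {
  start <- as_ymd(start)
  end <- as_ymd(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    abort("window start and end must be single valid dates")
  }
  if (end < start) abort("window end precedes window start")
  structure(
    list(start = start, end = end,
         length_days = as.integer(end - start) + 1L),
    class = "observation_window"
  )
}

#' The 2016 study window (366 days)
#' @return An [observation_window()] covering calendar year 2016.
#' @export
window_2016 <- function() observation_window("2016-01-01", "2016-12-31")

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window> %s .. %s (%d days)\n",
              format(x$start), format(x$end), x$length_days))
  invisible(x)
}

in_window <- function(dates, window) {
  dates >= window$start & dates <= window$end
}

# first quarter of the year following the window, for the ACQ fallback
next_q1 <- function(window) {
  yr <- as.integer(format(window$end, "%Y")) + 1L
  observation_window(as.Date(sprintf("%d-01-01", yr)),
                     as.Date(sprintf("%d-03-31", yr)))
}
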