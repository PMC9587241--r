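#' Prescription duration in days
#'
#' Theoretical days of use supplied by one prescription:
#' `floor(quantity / doses_per_day)`, with a minimum of one day. When either
#' field is missing the duration is *uncomputable* (`NA`), never a default:
#' uncomputable in-window ICS durations exclude the patient upstream.
#'
#' @param quantity Dose units dispensed as prescribed (vector, may be `NA`).
#' @param doses_per_day Prescribed daily dose units (vector, may be `NA`).
#' @return Integer vector of day counts, `NA` where uncomputable.
#' @export
duration_days <- function(quantity, doses_per_day) {
  if (any(!is.na(quantity) & quantity <= 0) ||
      any(!is.na(doses_per_day) & doses_per_day <= 0)) {
    abort("quantity and doses_per_day must be positive when present")
  }
  out <- as.integer(pmax(1, floor(quantity / doses_per_day)))
  out[is.na(quantity) | is.na(doses_per_day)] <- NA_integer_
  out
}

#' Covered days under the carry-over stock process
#'
#' Implements the medication-availability stock process behind CMA7: events
#' are processed chronologically; each adds its duration to a stock of
#' supply; every day with positive stock consumes one unit and is covered.
#' Oversupply from earlier prescriptions is therefore used before newer
#' supply. The closed form used here starts event *i*'s coverage at
#' `max(event_date_i, previous coverage end + 1)`; same-day events stack.
#'
#' @param event_dates Dates of supply events.
#' @param durations Positive integer durations (days) per event.
#' @param window An [observation_window()].
#' @param lookback_start Events before this date are ignored; carry-over from
#'   pre-window prescriptions on or after it is honoured.
#' @return Integer count of covered days inside the window.
#' @export
coverage_days <- function(event_dates, durations, window,
                          lookback_start = as.Date("2015-01-01")) {
  event_dates <- as_ymd(event_dates)
  lookback_start <- as_ymd(lookback_start)
  if (length(event_dates) != length(durations)) {
    abort("event_dates and durations differ in length")
  }
  if (anyNA(durations) || any(durations < 1)) {
    abort("durations must be computable and >= 1 day")
  }
  late <- event_dates > window$end
  if (any(late)) {
    warn(sprintf("ignoring %d supply event(s) after the window end", sum(late)))
  }
  keep <- !late & event_dates >= lookback_start
  if (!any(keep)) return(0L)
  d <- as.integer(event_dates[keep])
  u <- as.integer(durations[keep])
  ord <- order(d)
  d <- d[ord]; u <- u[ord]
  ws <- as.integer(window$start); we <- as.integer(window$end)
  covered <- 0L
  prev_end <- -.Machine$integer.max %/% 2L
  for (i in seq_along(d)) {
    start_i <- max(d[i], prev_end + 1L)
    end_i <- start_i + u[i] - 1L
    lo <- max(start_i, ws); hi <- min(end_i, we)
    if (hi >= lo) covered <- covered + (hi - lo + 1L)
    prev_end <- end_i
  }
  covered
}

#' CMA7: continuous medication availability with carry-over
#'
#' Divides the days of theoretical use (window days minus gap days, with
#' carry-over for prescriptions within and before the window) by the window
#' length, expressed as a percentage. All ICS-containing products pool into
#' one supply stream.
#'
#' @param events Tibble of a patient's ICS-stream prescriptions
#'   (`issue_date`, `quantity`, `doses_per_day`).
#' @param window An [observation_window()].
#' @param lookback_start Start of the pre-window carry-over lookback.
#' @return A one-row tibble: `cma7_pct`, `covered_days`, `gap_days`,
#'   `category`, and `no_events` (flag: no supply in or before the window).
#' @export
cma7 <- function(events, window, lookback_start = as.Date("2015-01-01")) {
  usable <- events[in_window(events$issue_date, window) |
                     events$issue_date < window$start, , drop = FALSE]
  if (nrow(usable) == 0L) {
    return(tibble::tibble(cma7_pct = 0, covered_days = 0L,
                          gap_days = window$length_days,
                          category = adherence_category(0), no_events = TRUE))
  }
  dur <- duration_days(usable$quantity, usable$doses_per_day)
  if (anyNA(dur[in_window(usable$issue_date, window)])) {
    abort("uncomputable in-window ICS duration: exclude the patient upstream")
  }
  keep <- !is.na(dur)
  cov <- coverage_days(usable$issue_date[keep], dur[keep], window, lookback_start)
  pct <- 100 * cov / window$length_days
  tibble::tibble(cma7_pct = pct, covered_days = cov,
                 gap_days = window$length_days - cov,
                 category = adherence_category(pct), no_events = FALSE)
}

#' CMA1: uncapped medication possession ratio
#'
#' Total days supplied by in-window prescriptions divided by the window
#' length, as a percentage; unlike CMA7 this ignores carry-over and may
#' exceed 100.
#'
#' @inheritParams cma7
#' @return A percentage (may exceed 100).
#' @export
cma1 <- function(events, window) {
  inw <- events[in_window(events$issue_date, window), , drop = FALSE]
  if (nrow(inw) == 0L) return(0)
  dur <- duration_days(inw$quantity, inw$doses_per_day)
  if (anyNA(dur)) abort("uncomputable in-window duration")
  100 * sum(dur) / window$length_days
}

adherence_levels <- c("<=50", "51-60", "61-70", "71-80", "81-90", "91-100")

#' Six-category adherence binning
#'
#' Bins the continuous CMA7 percentage into `<=50`, `51-60`, `61-70`,
#' `71-80`, `81-90`, `91-100`. Intervals are half-open on the continuous
#' scale (`[0, 50]`, then `(50, 60]` and so on), so non-integer values such
#' as 50.4, which the printed integer labels leave undefined, bin as `51-60`.
#'
#' @param cma7_pct Numeric vector in `[0, 100]`.
#' @return Factor with the six adherence levels.
#' @export
adherence_category <- function(cma7_pct) {
  if (any(!is.na(cma7_pct) & (cma7_pct < 0 | cma7_pct > 100))) {
    abort("cma7_pct must lie in [0, 100]")
  }
  cut(cma7_pct, breaks = c(0, 50, 60, 70, 80, 90, 100),
      labels = adherence_levels, include.lowest = TRUE, right = TRUE)
}

#' Per-patient CMA7 over the pooled ICS stream
#'
#' Filters a prescription table to ICS-containing products (ICS mono and
#' fixed ICS/LABA combinations), pools them into one supply stream per
#' patient, and computes CMA7. Patients absent from the ICS stream receive
#' `no_events = TRUE` and an `NA` adherence category (no controller
#' medication implies no adherence value, as for SABA-only patients).
#'
#' @param prescriptions Prescription tibble (multiple patients).
#' @param patient_ids Patients to evaluate (default: all in the table).
#' @param window An [observation_window()].
#' @param lookback_start Start of the carry-over lookback.
#' @param config Code-list configuration.
#' @return Tibble: `patient_id`, `cma7_pct`, `covered_days`, `gap_days`,
#'   `category`, `no_events`; `cma7_pct` and `category` are `NA` for
#'   patients without ICS supply.
#' @export
cma7_by_patient <- function(prescriptions, patient_ids = NULL, window,
                            lookback_start = as.Date("2015-01-01"),
                            config = code_config()) {
  ics <- prescriptions[is_ics_class(classify_atc(prescriptions$atc, config)), ,
                       drop = FALSE]
  patient_ids <- patient_ids %||% unique(prescriptions$patient_id)
  streams <- split(ics, factor(ics$patient_id, levels = patient_ids))
  rows <- purrr::map(patient_ids, function(pid) {
    res <- cma7(streams[[pid]], window, lookback_start)
    res$patient_id <- pid
    res
  })
  out <- dplyr::bind_rows(rows)
  out$cma7_pct[out$no_events] <- NA_real_
  out$category[out$no_events] <- NA
  dplyr::relocate(out, "patient_id")
}
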