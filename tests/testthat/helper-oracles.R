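# Independent oracles: literal day-by-day / brute-force implementations kept
# deliberately separate from the package's closed-form algorithms.

# day-by-day stock simulation of medication availability: each event adds its
# duration to the stock; every day with positive stock consumes one unit
oracle_coverage_days <- function(event_dates, durations, window,
                                 lookback_start = as.Date("2015-01-01")) {
  d <- as.integer(as.Date(event_dates))
  keep <- d >= as.integer(lookback_start) & d <= as.integer(window$end)
  d <- d[keep]
  u <- durations[keep]
  if (length(d) == 0L) return(0L)
  ws <- as.integer(window$start)
  we <- as.integer(window$end)
  covered <- 0L
  stock <- 0L
  for (day in min(c(d, ws)):we) {
    stock <- stock + sum(u[d == day])
    if (stock >= 1L) {
      stock <- stock - 1L
      if (day >= ws) covered <- covered + 1L
    }
  }
  covered
}

# transitive-closure clustering of prescription dates: two dates are linked
# when at most gap_days apart; courses are the connected components
oracle_course_count <- function(dates, gap_days = 14L) {
  d <- as.integer(as.Date(dates))
  n <- length(d)
  if (n == 0L) return(0L)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- abs(d - d[i]) <= gap_days
      target <- min(comp[linked])
      if (any(comp[linked] != target)) {
        comp[linked] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

random_supply_stream <- function(max_events = 10L) {
  n <- sample(seq_len(max_events), 1)
  list(
    dates = as.Date("2015-01-01") + sample(0:730, n, replace = TRUE),
    durations = sample(1:120, n, replace = TRUE)
  )
}
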