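# Independent oracles used to cross-check the implementation.

# Day-by-day walk over the calendar: a supply tank is refilled (no
# stockpiling: max of remaining and new supply) on each claim day and drained
# one day at a time; a claim opens a new episode when the tank has been dry
# for more than gap_days. Returns start/end (numeric days), n_claims and
# total days per episode.
oracle_chain <- function(rx_day, days_supplied, gap_days) {
  o <- order(rx_day)
  rx_day <- as.numeric(rx_day)[o]
  days_supplied <- days_supplied[o]
  eps <- list()
  cur <- NULL
  tank <- 0
  dry <- Inf
  for (t in seq(min(rx_day), max(rx_day))) {
    for (j in which(rx_day == t)) {
      if (is.null(cur) || dry > gap_days) {
        if (!is.null(cur)) eps[[length(eps) + 1]] <- cur
        cur <- list(start = t, end = t + days_supplied[j], n = 0L, tot = 0L)
        tank <- 0
        dry <- 0  # supply begins today
      }
      tank <- max(tank, days_supplied[j])
      cur$n <- cur$n + 1L
      cur$tot <- cur$tot + as.integer(days_supplied[j])
      cur$end <- max(cur$end, t + days_supplied[j])
    }
    if (tank > 0) {
      tank <- tank - 1
      dry <- 0
    } else {
      dry <- dry + 1
    }
  }
  eps[[length(eps) + 1]] <- cur
  data.frame(start = vapply(eps, `[[`, numeric(1), "start"),
             end = vapply(eps, `[[`, numeric(1), "end"),
             n_claims = vapply(eps, `[[`, integer(1), "n"),
             total_days = vapply(eps, `[[`, integer(1), "tot"))
}

# Exhaustive enumeration of all month windows of length run_months on the
# gap-filled calendar; independent of the rle-based detector.
oracle_moh <- function(month_idx, triptan_ergot, analgesic, thresholds) {
  grid <- seq(min(month_idx), max(month_idx))
  over <- vapply(grid, function(m) {
    j <- which(month_idx == m)
    length(j) > 0 &&
      (triptan_ergot[j] >= thresholds$triptan_ergot_days_per_month ||
         analgesic[j] >= thresholds$analgesic_days_per_month)
  }, logical(1))
  runs <- thresholds$run_months
  first_start <- NA_integer_
  for (s in seq_along(grid)) {
    if (s + runs - 1 > length(grid)) break
    if (all(over[s:(s + runs - 1)])) {
      first_start <- grid[s]
      break
    }
  }
  # extend the first qualifying run to its maximal length
  run_len <- 0L
  if (!is.na(first_start)) {
    s <- match(first_start, grid)
    while (s + run_len <= length(grid) && over[s + run_len]) {
      run_len <- run_len + 1L
    }
    # the run may begin before first_start ends; detector reports the whole
    # maximal run containing it, which starts at the first overuse month of
    # that stretch
    while (s > 1 && over[s - 1]) {
      s <- s - 1
      run_len <- run_len + 1L
      first_start <- grid[s]
    }
  }
  list(case2 = !is.na(first_start), first_month_idx = first_start,
       run_len = run_len)
}

# random prescription claims for one patient / one molecule
random_claims <- function(n_claims, molecule = "sumatriptan",
                          max_day = 400, max_supply = 40,
                          origin = as.Date("2020-01-01")) {
  tibble::tibble(
    patient_id = "PX",
    rx_date = origin + sample.int(max_day, n_claims, replace = TRUE),
    molecule = molecule,
    days_supplied = sample.int(max_supply, n_claims, replace = TRUE))
}
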