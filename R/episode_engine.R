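# Prescription-episode (drug era) construction and the per-month acute-use
# exposure calendar. All date arithmetic is in whole days.

month_floor <- function(d) as.Date(format(d, "%Y-%m-01"))

# months since year 0, for consecutive-calendar-month arithmetic
month_index <- function(d) {
  as.integer(format(d, "%Y")) * 12L + as.integer(format(d, "%m")) - 1L
}

days_in_month <- function(month_start) {
  vapply(seq_along(month_start), function(i) {
    as.integer(seq(month_start[i], by = "1 month", length.out = 2)[2] -
                 month_start[i])
  }, integer(1))
}

#' Chain prescription claims into continuous-use episodes
#'
#' Builds maximal continuous-prescription intervals (drug eras) per patient
#' and drug key, at molecule or class level. Claims are processed in date
#' order; a claim joins the open episode of its key when its date falls on
#' or before the episode's supply-exhaustion date plus `gap_days` (the
#' refill grace period), otherwise a new episode opens. The supply-end date
#' extends to the later of the current end and claim date + days supplied,
#' so overlapping refills do not stockpile unused days by default.
#'
#' @param prescriptions Prescription claims tibble (`patient_id`, `rx_date`,
#'   `molecule`, `days_supplied`).
#' @param codelist Codelist tibble used to resolve drug classes.
#' @param level `"molecule"` or `"class"`: granularity of the chaining key.
#' @param gap_days Maximum gap, in days, between supply exhaustion and the
#'   next refill for the prescription to count as continuous (default 60).
#' @param stockpile If `TRUE`, an overlapping refill adds its full supply on
#'   top of the remaining days instead of extending by `max()`.
#' @param keep_other Keep claims whose molecule maps to class `"other"`
#'   (default `FALSE`: they are excluded from migraine-treatment logic).
#' @return Tibble of episodes: `patient_id`, `level`, `key`, `drug_class`,
#'   `start_date`, `supply_end_date`, `period_days` (supply end minus
#'   start), `n_claims`, `total_days_supplied`.
#' @export
chain_episodes <- function(prescriptions, codelist = default_codelist(),
                           level = c("molecule", "class"), gap_days = 60,
                           stockpile = FALSE, keep_other = FALSE) {
  level <- match.arg(level)
  empty <- tibble(
    patient_id = character(), level = character(), key = character(),
    drug_class = character(),
    start_date = as.Date(character()), supply_end_date = as.Date(character()),
    period_days = integer(), n_claims = integer(),
    total_days_supplied = integer())
  if (nrow(prescriptions) == 0) return(empty)

  cls <- classify_molecule(prescriptions$molecule, codelist)
  rx <- mutate(prescriptions, drug_class = cls$drug_class)
  if (!keep_other) rx <- filter(rx, .data$drug_class != "other")
  if (nrow(rx) == 0) return(empty)
  rx$key <- if (level == "molecule") rx$molecule else rx$drug_class
  rx <- arrange(rx, .data$patient_id, .data$key, .data$rx_date,
                .data$days_supplied)

  grp <- paste(rx$patient_id, rx$key, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(rx)), grp), function(idx) {
    d <- rx[idx, ]
    n <- nrow(d)
    ep <- integer(n)
    starts <- ends <- numeric(n)
    cur <- 0L
    open_end <- -Inf
    for (i in seq_len(n)) {
      t0 <- as.numeric(d$rx_date[i])
      if (t0 > open_end + gap_days) {
        cur <- cur + 1L
        starts[cur] <- t0
        open_end <- t0 + d$days_supplied[i]
      } else if (stockpile) {
        open_end <- max(open_end, t0) + d$days_supplied[i]
      } else {
        open_end <- max(open_end, t0 + d$days_supplied[i])
      }
      ep[i] <- cur
      ends[cur] <- open_end
    }
    tibble(
      patient_id = d$patient_id[1], key = d$key[1],
      drug_class = d$drug_class[1],
      start_date = as.Date(starts[seq_len(cur)], origin = "1970-01-01"),
      supply_end_date = as.Date(ends[seq_len(cur)], origin = "1970-01-01"),
      n_claims = as.integer(tabulate(ep, cur)),
      total_days_supplied = as.integer(
        vapply(seq_len(cur), function(k) sum(d$days_supplied[ep == k]),
               numeric(1))))
  })
  out <- bind_rows(pieces)
  out <- mutate(out, level = level,
                period_days = as.integer(.data$supply_end_date -
                                           .data$start_date))
  out <- select(out, "patient_id", "level", "key", "drug_class",
                "start_date", "supply_end_date", "period_days", "n_claims",
                "total_days_supplied")
  arrange(out, .data$patient_id, .data$key, .data$start_date)
}

#' Summarise prescription periods by preventive class
#'
#' For each requested drug class, takes the first episode per patient and
#' summarises its prescription period (days from first prescription to
#' supply exhaustion) as median and interquartile range. Quantiles use
#' linear interpolation (R type 7).
#'
#' @param episodes Episode tibble from [chain_episodes()] (class level for
#'   the usual report).
#' @param classes Drug classes to summarise (default: the preventive
#'   classes).
#' @return Tibble with `drug_class`, `n_patients`, `p25`, `median`, `p75`
#'   (days). Classes with no episodes are omitted; an empty input yields an
#'   empty summary.
#' @export
summarize_prescription_periods <- function(episodes,
                                           classes = PREVENTIVE_CLASSES) {
  ep <- filter(episodes, .data$drug_class %in% classes)
  if (nrow(ep) == 0) {
    return(tibble(drug_class = character(), n_patients = integer(),
                  p25 = numeric(), median = numeric(), p75 = numeric()))
  }
  first_ep <- ep %>%
    arrange(.data$start_date) %>%
    group_by(.data$patient_id, .data$drug_class) %>%
    dplyr::slice(1) %>%
    ungroup()
  first_ep %>%
    group_by(.data$drug_class) %>%
    summarise(
      n_patients = n(),
      p25 = unname(quantile(.data$period_days, 0.25, type = 7)),
      median = unname(quantile(.data$period_days, 0.5, type = 7)),
      p75 = unname(quantile(.data$period_days, 0.75, type = 7)),
      .groups = "drop")
}

#' Per-month acute drug exposure calendar
#'
#' Attributes the full supply of every acute prescription claim to the
#' calendar month of its date (claims databases record as-needed scripts as
#' day counts, and use is assumed to fall within the month of prescription),
#' then sums per patient, month and acute class. Each reported value is
#' capped at the length of the month. The triptan + ergotamine combined sum
#' and the total across all acute classes are computed from the uncapped
#' sums before their own cap is applied.
#'
#' @param prescriptions Prescription claims tibble.
#' @param codelist Codelist tibble.
#' @return Tibble with `patient_id`, `month` (first day of month),
#'   `acetaminophen_nsaid`, `triptan`, `ergotamine`, `triptan_ergotamine`,
#'   `total_acute` (integer days, each capped at the month's day count).
#' @export
monthly_acute_days <- function(prescriptions, codelist = default_codelist()) {
  empty <- tibble(patient_id = character(), month = as.Date(character()),
                  acetaminophen_nsaid = integer(), triptan = integer(),
                  ergotamine = integer(), triptan_ergotamine = integer(),
                  total_acute = integer())
  if (nrow(prescriptions) == 0) return(empty)
  cls <- classify_molecule(prescriptions$molecule, codelist)
  rx <- prescriptions %>%
    mutate(drug_class = cls$drug_class) %>%
    filter(.data$drug_class %in% ACUTE_CLASSES) %>%
    mutate(month = month_floor(.data$rx_date))
  if (nrow(rx) == 0) return(empty)
  raw <- rx %>%
    group_by(.data$patient_id, .data$month, .data$drug_class) %>%
    summarise(days = sum(.data$days_supplied), .groups = "drop")
  wide <- tidyr::pivot_wider(raw, names_from = "drug_class",
                             values_from = "days", values_fill = 0L)
  for (cl in ACUTE_CLASSES) {
    if (is.null(wide[[cl]])) wide[[cl]] <- 0L
  }
  cap <- days_in_month(wide$month)
  wide %>%
    mutate(
      triptan_ergotamine = pmin(.data$triptan + .data$ergotamine, cap),
      total_acute = pmin(.data$acetaminophen_nsaid + .data$triptan +
                           .data$ergotamine, cap),
      acetaminophen_nsaid = pmin(.data$acetaminophen_nsaid, cap),
      triptan = pmin(.data$triptan, cap),
      ergotamine = pmin(.data$ergotamine, cap)) %>%
    select("patient_id", "month", "acetaminophen_nsaid", "triptan",
           "ergotamine", "triptan_ergotamine", "total_acute") %>%
    arrange(.data$patient_id, .data$month)
}
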