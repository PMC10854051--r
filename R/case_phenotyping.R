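# Rule-based phenotypes of patients potentially not managed well:
#   Case 1  - at least one triptan switch
#   Case 2  - prescription pattern with potential risk of medication-overuse
#             headache (MOH), ICHD-3 convention: triptans/ergotamine on >= 10
#             days/month or simple analgesics on >= 15 days/month over >= 3
#             consecutive calendar months
#   Case 3  - no decrease in mean monthly acute drug days after starting
#             preventive treatment, among patients who continued the
#             preventive for at least 3 months (3-1 conventional classes,
#             3-2 anti-CGRP mAbs)

#' MOH detection thresholds
#'
#' The numeric thresholds follow the ICHD-3 convention for medication
#' overuse: triptans/ergotamine on 10 or more days per month, simple
#' analgesics (acetaminophen/NSAIDs) on 15 or more days per month, over at
#' least `run_months` consecutive calendar months. All three are exposed as
#' parameters.
#'
#' @param triptan_ergot_days_per_month Monthly day threshold for the
#'   combined triptan + ergotamine exposure (default 10).
#' @param analgesic_days_per_month Monthly day threshold for
#'   acetaminophen/NSAID exposure (default 15).
#' @param run_months Required number of consecutive overuse months
#'   (default 3).
#' @return A named list of thresholds.
#' @export
moh_thresholds <- function(triptan_ergot_days_per_month = 10,
                           analgesic_days_per_month = 15,
                           run_months = 3) {
  stopifnot(triptan_ergot_days_per_month > 0,
            analgesic_days_per_month > 0, run_months > 0)
  list(triptan_ergot_days_per_month = triptan_ergot_days_per_month,
       analgesic_days_per_month = analgesic_days_per_month,
       run_months = run_months)
}

#' Detect triptan switches (Case 1)
#'
#' A switch is a molecule-level triptan episode B starting on or after the
#' supply-end date of an episode of a different triptan molecule A, and no
#' later than `switch_window_days` after it. Distinct triptans with
#' overlapping episodes (B starting before A's supply end) count as an
#' addition, not a switch, unless `count_overlap_as_switch = TRUE`. The
#' first switch per patient is reported.
#'
#' @param molecule_episodes Molecule-level episode tibble from
#'   [chain_episodes()].
#' @param switch_window_days Maximum days between supply end of the old
#'   triptan and start of the new one (default 60).
#' @param count_overlap_as_switch Treat overlapping distinct triptans as a
#'   switch (default `FALSE`).
#' @return Tibble with `patient_id`, `case1`, `from_molecule`,
#'   `to_molecule`, `switch_date`, covering every patient with a triptan
#'   episode.
#' @export
detect_triptan_switch <- function(molecule_episodes, switch_window_days = 60,
                                  count_overlap_as_switch = FALSE) {
  tript <- filter(molecule_episodes, .data$drug_class == "triptan")
  empty <- tibble(patient_id = character(), case1 = logical(),
                  from_molecule = character(), to_molecule = character(),
                  switch_date = as.Date(character()))
  if (nrow(tript) == 0) return(empty)
  pieces <- lapply(split(tript, tript$patient_id), function(d) {
    d <- arrange(d, .data$start_date, .data$key)
    best <- NULL
    if (nrow(d) > 1) {
      for (b in seq_len(nrow(d))) {
        for (a in seq_len(nrow(d))) {
          if (d$key[a] == d$key[b]) next
          gap <- as.integer(d$start_date[b] - d$supply_end_date[a])
          is_switch <- (gap >= 0 && gap <= switch_window_days) ||
            (count_overlap_as_switch && d$start_date[b] > d$start_date[a] &&
               gap < 0)
          if (is_switch && (is.null(best) ||
                            d$start_date[b] < best$switch_date)) {
            best <- list(from = d$key[a], to = d$key[b],
                         switch_date = d$start_date[b])
          }
        }
      }
    }
    if (is.null(best)) {
      tibble(patient_id = d$patient_id[1], case1 = FALSE,
             from_molecule = NA_character_, to_molecule = NA_character_,
             switch_date = as.Date(NA))
    } else {
      tibble(patient_id = d$patient_id[1], case1 = TRUE,
             from_molecule = best$from, to_molecule = best$to,
             switch_date = best$switch_date)
    }
  })
  bind_rows(pieces)
}

# overuse flag per calendar month on a gap-filled month grid
overuse_months <- function(exposure_patient, thresholds) {
  mi <- month_index(exposure_patient$month)
  grid <- seq(min(mi), max(mi))
  over <- rep(FALSE, length(grid))
  hit <- exposure_patient$triptan_ergotamine >=
    thresholds$triptan_ergot_days_per_month |
    exposure_patient$acetaminophen_nsaid >=
    thresholds$analgesic_days_per_month
  over[match(mi, grid)] <- hit
  list(grid = grid, over = over)
}

#' Detect prescription patterns at risk of MOH (Case 2)
#'
#' Flags a patient when at least `run_months` consecutive calendar months
#' are overuse months: combined triptan + ergotamine days at or above the
#' triptan threshold, or acetaminophen/NSAID days at or above the analgesic
#' threshold. Months without any acute prescription break a run. The first
#' qualifying run is reported.
#'
#' @param monthly_exposure Output of [monthly_acute_days()].
#' @param thresholds A [moh_thresholds()] list.
#' @return Tibble with `patient_id`, `case2`, `first_overuse_month` (first
#'   month of the first qualifying run) and `n_consecutive_overuse_months`
#'   (length of that run), covering every patient in the exposure series.
#' @export
detect_moh_risk <- function(monthly_exposure, thresholds = moh_thresholds()) {
  empty <- tibble(patient_id = character(), case2 = logical(),
                  first_overuse_month = as.Date(character()),
                  n_consecutive_overuse_months = integer())
  if (nrow(monthly_exposure) == 0) return(empty)
  pieces <- lapply(split(monthly_exposure, monthly_exposure$patient_id),
                   function(d) {
    om <- overuse_months(d, thresholds)
    r <- rle(om$over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    qual <- which(r$values & r$lengths >= thresholds$run_months)
    if (length(qual) == 0) {
      tibble(patient_id = d$patient_id[1], case2 = FALSE,
             first_overuse_month = as.Date(NA),
             n_consecutive_overuse_months = 0L)
    } else {
      k <- qual[1]
      m0 <- om$grid[starts[k]]
      tibble(patient_id = d$patient_id[1], case2 = TRUE,
             first_overuse_month = as.Date(
               sprintf("%04d-%02d-01", m0 %/% 12L, m0 %% 12L + 1L)),
             n_consecutive_overuse_months = r$lengths[k])
    }
  })
  bind_rows(pieces)
}

#' Detect no decrease in acute use after preventive start (Case 3)
#'
#' Eligibility requires the patient's first preventive episode of the group
#' (conventional preventive classes, or anti-CGRP mAbs) to have a
#' prescription period of at least `continuation_days` (continued at least
#' 3 months by default). Among eligible patients the flag is raised when
#' the mean total acute days per calendar month over the `window_months`
#' months starting with the month of the preventive start is greater than
#' or equal to the mean over the `window_months` months strictly before it
#' ("no decrease" includes equality). Months without acute prescriptions
#' count as zero days.
#'
#' @param class_episodes Class-level episode tibble.
#' @param monthly_exposure Output of [monthly_acute_days()].
#' @param group `"conventional"` or `"anti_cgrp_mab"`.
#' @param continuation_days Minimum first-episode period (default 90).
#' @param window_months Width of the before/after comparison windows in
#'   calendar months (default 3).
#' @return Tibble with `patient_id`, `eligible`, `case3`,
#'   `preventive_start`, `mean_acute_days_before`, `mean_acute_days_after`,
#'   covering every patient with an episode of the group.
#' @export
detect_case3 <- function(class_episodes, monthly_exposure,
                         group = c("conventional", "anti_cgrp_mab"),
                         continuation_days = 90, window_months = 3) {
  group <- match.arg(group)
  classes <- if (group == "conventional") CONVENTIONAL_PREVENTIVE
             else "anti_cgrp_mab"
  prev <- filter(class_episodes, .data$drug_class %in% classes)
  empty <- tibble(patient_id = character(), eligible = logical(),
                  case3 = logical(), preventive_start = as.Date(character()),
                  mean_acute_days_before = numeric(),
                  mean_acute_days_after = numeric())
  if (nrow(prev) == 0) return(empty)
  first_prev <- prev %>%
    arrange(.data$start_date, .data$key) %>%
    group_by(.data$patient_id) %>%
    dplyr::slice(1) %>%
    ungroup()
  exp_split <- split(monthly_exposure, monthly_exposure$patient_id)
  pieces <- lapply(seq_len(nrow(first_prev)), function(i) {
    pid <- first_prev$patient_id[i]
    eligible <- first_prev$period_days[i] >= continuation_days
    m0 <- month_index(first_prev$start_date[i])
    ex <- exp_split[[pid]]
    month_total <- function(m) {
      if (is.null(ex)) return(0)
      j <- which(month_index(ex$month) == m)
      if (length(j) == 0) 0 else ex$total_acute[j]
    }
    before <- mean(vapply(seq(m0 - window_months, m0 - 1), month_total,
                          numeric(1)))
    after <- mean(vapply(seq(m0, m0 + window_months - 1), month_total,
                         numeric(1)))
    tibble(patient_id = pid, eligible = eligible,
           case3 = eligible && after >= before,
           preventive_start = first_prev$start_date[i],
           mean_acute_days_before = before, mean_acute_days_after = after)
  })
  bind_rows(pieces)
}

#' Compute all case flags for a population
#'
#' Runs the three detectors over a patient population and assembles one row
#' per patient with every flag and its evidence. Patients without the
#' relevant exposure default to `FALSE`/not eligible.
#'
#' @param patient_ids Character vector of the population (normally the
#'   12-month follow-up population).
#' @param molecule_episodes,class_episodes,monthly_exposure Prepared inputs
#'   from [chain_episodes()] and [monthly_acute_days()].
#' @param thresholds A [moh_thresholds()] list.
#' @param switch_window_days,continuation_days,window_months Detector
#'   parameters, see the individual detectors.
#' @return Tibble keyed by `patient_id` with columns `case1`, `case2`,
#'   `case3_eligible_conventional`, `case3_1`, `case3_eligible_mab`,
#'   `case3_2` and their evidence columns.
#' @export
compute_case_flags <- function(patient_ids, molecule_episodes,
                               class_episodes, monthly_exposure,
                               thresholds = moh_thresholds(),
                               switch_window_days = 60,
                               continuation_days = 90, window_months = 3) {
  keep <- function(d) filter(d, .data$patient_id %in% patient_ids)
  c1 <- detect_triptan_switch(keep(molecule_episodes), switch_window_days)
  c2 <- detect_moh_risk(keep(monthly_exposure), thresholds)
  c3c <- detect_case3(keep(class_episodes), keep(monthly_exposure),
                      "conventional", continuation_days, window_months)
  c3m <- detect_case3(keep(class_episodes), keep(monthly_exposure),
                      "anti_cgrp_mab", continuation_days, window_months)
  out <- tibble(patient_id = sort(unique(patient_ids))) %>%
    left_join(c1, by = "patient_id") %>%
    left_join(rename(c2, moh_run_months = "n_consecutive_overuse_months"),
              by = "patient_id") %>%
    left_join(rename(c3c, case3_eligible_conventional = "eligible",
                     case3_1 = "case3",
                     conv_preventive_start = "preventive_start",
                     conv_acute_before = "mean_acute_days_before",
                     conv_acute_after = "mean_acute_days_after"),
              by = "patient_id") %>%
    left_join(rename(c3m, case3_eligible_mab = "eligible",
                     case3_2 = "case3",
                     mab_preventive_start = "preventive_start",
                     mab_acute_before = "mean_acute_days_before",
                     mab_acute_after = "mean_acute_days_after"),
              by = "patient_id")
  flag_cols <- c("case1", "case2", "case3_eligible_conventional", "case3_1",
                 "case3_eligible_mab", "case3_2")
  for (cc in flag_cols) out[[cc]] <- !is.na(out[[cc]]) & out[[cc]]
  out$moh_run_months[is.na(out$moh_run_months)] <- 0L
  out
}

#' Summarise the case phenotypes
#'
#' One row per group (total population, Case 1, Case 2, Case 3-1, Case
#' 3-2): patient count, percentage (of the population for Cases 1-2, of the
#' group's eligible patients for Cases 3-1/3-2), age mean and SD, sex
#' split, comorbidity prevalences, and the share receiving any preventive
#' treatment during follow-up.
#'
#' @param flags Output of [compute_case_flags()].
#' @param population Cohort tibble (normally the 12-month follow-up
#'   population) with `patient_id`, `age_at_index`, `sex` and `cm_*`
#'   columns.
#' @param preventive_users Character vector of patients with any preventive
#'   episode during follow-up.
#' @return Tibble with one row per group and summary columns; empty
#'   population yields an empty table.
#' @export
case_summary <- function(flags, population, preventive_users = character()) {
  if (nrow(population) == 0) {
    return(tibble(group = character(), n = integer(),
                  denominator = integer(), pct = numeric()))
  }
  fl <- left_join(select(population, "patient_id", "age_at_index", "sex",
                         dplyr::starts_with("cm_")),
                  flags, by = "patient_id")
  n_pop <- nrow(fl)
  groups <- list(
    total   = list(sel = rep(TRUE, n_pop), den = n_pop),
    case1   = list(sel = fl$case1, den = n_pop),
    case2   = list(sel = fl$case2, den = n_pop),
    case3_1 = list(sel = fl$case3_1,
                   den = sum(fl$case3_eligible_conventional)),
    case3_2 = list(sel = fl$case3_2, den = sum(fl$case3_eligible_mab)))
  cm_cols <- grep("^cm_", names(fl), value = TRUE)
  pieces <- lapply(names(groups), function(g) {
    sel <- groups[[g]]$sel
    den <- groups[[g]]$den
    d <- fl[sel, ]
    row <- tibble(
      group = g, n = nrow(d), denominator = den,
      pct = if (den > 0) pct(nrow(d), den) else NA_real_,
      age_mean = mean(d$age_at_index), age_sd = stats::sd(d$age_at_index),
      n_female = sum(d$sex == "female"),
      pct_female = if (nrow(d) > 0) pct(sum(d$sex == "female"), nrow(d))
                   else NA_real_,
      n_preventive = sum(d$patient_id %in% preventive_users),
      pct_preventive = if (nrow(d) > 0)
        pct(sum(d$patient_id %in% preventive_users), nrow(d)) else NA_real_)
    for (cc in cm_cols) {
      row[[paste0("pct_", sub("^cm_", "", cc))]] <-
        if (nrow(d) > 0) pct(sum(d[[cc]]), nrow(d)) else NA_real_
    }
    row
  })
  bind_rows(pieces)
}
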