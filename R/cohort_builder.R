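# Headache / migraine cohort construction: index dates, baseline enrollment
# and comorbidity windows, follow-up, facility banding and imaging
# attribution.

HEADACHE_ICD <- function(icd10) icd10 == "R51" | startsWith(icd10, "G43")

#' Classify a facility into the bed-count band
#'
#' Clinics (CP) have 19 or fewer beds, hospitals (HP) 20 or more, per the
#' banding used for Japanese medical institutions; hospitals are further
#' split at 100, 200, 300 and 500 beds.
#'
#' @param bed_count Non-negative integer vector of bed counts.
#' @return Character vector of bands: `CP_0_19`, `HP_20_99`, `HP_100_199`,
#'   `HP_200_299`, `HP_300_499`, `HP_500_plus`.
#' @export
classify_facility_band <- function(bed_count) {
  if (any(is.na(bed_count) | bed_count < 0)) {
    stop("bed_count must be non-negative", call. = FALSE)
  }
  cut(bed_count, breaks = c(-1, 19, 99, 199, 299, 499, Inf),
      labels = FACILITY_BANDS) |> as.character()
}

# age at a given date from birth year alone, mid-year (June 30) birthday
# convention
age_at_date <- function(birth_year, date) {
  age <- as.integer(format(date, "%Y")) - birth_year
  age - as.integer(format(date, "%m%d") < "0630")
}

# last observed visit per patient: latest date on any claim table
last_visit_dates <- function(bundle) {
  visits <- bind_rows(
    select(bundle$diagnoses, "patient_id", date = "service_date"),
    select(bundle$prescriptions, "patient_id", date = "rx_date"),
    select(bundle$procedures, "patient_id", date = "service_date"))
  if (nrow(visits) == 0) {
    return(tibble(patient_id = character(), last_visit = as.Date(character())))
  }
  visits %>%
    group_by(.data$patient_id) %>%
    summarise(last_visit = max(.data$date), .groups = "drop")
}

# TRUE when one enrollment span covers [date - baseline_days, date]
has_baseline_enrollment <- function(enrollment, patient_id, date,
                                    baseline_days) {
  vapply(seq_along(patient_id), function(i) {
    sp <- enrollment[enrollment$patient_id == patient_id[i], ]
    any(sp$start_date <= date[i] - baseline_days &
          (is.na(sp$end_date) | sp$end_date >= date[i]))
  }, logical(1))
}

#' Flag baseline comorbidities
#'
#' For each patient/index pair, flags each comorbidity group that has at
#' least one confirmed (non-suspected) diagnosis claim whose ICD-10 code
#' falls in the group's prefix set during the baseline window
#' `[index - baseline_days, index)`. Also derives the pooled cardiovascular
#' flag (union of the cerebrovascular, hypertension, ischemic-heart and
#' peripheral-vascular groups) and an any-comorbidity flag.
#'
#' @param bundle A `claims_bundle`.
#' @param patient_id,index_date Parallel vectors defining the patients and
#'   their index dates.
#' @param comorbidity_map Named list of prefix sets, see
#'   [default_comorbidity_map()].
#' @param baseline_days Length of the baseline window in days (default 183).
#' @return Tibble with `patient_id` and one logical `cm_<group>` column per
#'   group plus `cm_any_cardiovascular` and `cm_any`.
#' @export
flag_baseline_comorbidities <- function(bundle, patient_id, index_date,
                                        comorbidity_map =
                                          default_comorbidity_map(),
                                        baseline_days = 183) {
  dx <- filter(bundle$diagnoses, !.data$suspected,
               .data$patient_id %in% .env$patient_id)
  out <- tibble(patient_id = patient_id)
  idx <- setNames(index_date, patient_id)
  in_window <- dx$service_date >= idx[dx$patient_id] - baseline_days &
    dx$service_date < idx[dx$patient_id]
  dx <- dx[in_window, ]
  for (g in names(comorbidity_map)) {
    spec <- comorbidity_map[[g]]
    hit <- rep(FALSE, nrow(dx))
    for (p in spec$include) hit <- hit | startsWith(dx$icd10, p)
    for (p in spec$exclude) hit <- hit & !startsWith(dx$icd10, p)
    out[[paste0("cm_", g)]] <- out$patient_id %in% dx$patient_id[hit]
  }
  cvd_cols <- paste0("cm_", CARDIOVASCULAR_GROUPS)
  out$cm_any_cardiovascular <- Reduce(`|`, out[cvd_cols])
  grp_cols <- paste0("cm_", names(comorbidity_map))
  out$cm_any <- Reduce(`|`, out[grp_cols])
  out
}

#' Attribute imaging tests around the initial diagnosis
#'
#' A patient counts as imaged when at least one CT or MRI procedure claim
#' falls within `window_days` days (inclusive) on either side of the first
#' headache/migraine diagnosis claim date (the actual claim date, not the
#' month-floored index). The imaging site is classified by the performing
#' facility's band: CP, HP, or both when imaging occurred at both kinds of
#' facility.
#'
#' @param bundle A `claims_bundle`.
#' @param patient_id,first_dx_date Parallel vectors of patients and their
#'   first diagnosis claim dates.
#' @param window_days Half-width of the window in days (default 90, i.e. 3
#'   months before and after).
#' @return Tibble with `patient_id`, `imaging_done` (logical) and
#'   `imaging_site` (`"CP"`, `"HP"`, `"both"`, `"none"`).
#' @export
attribute_imaging <- function(bundle, patient_id, first_dx_date,
                              window_days = 90) {
  fac_band <- setNames(classify_facility_band(bundle$facilities$bed_count),
                       bundle$facilities$facility_id)
  pr <- filter(bundle$procedures, .data$patient_id %in% .env$patient_id)
  anchor <- setNames(first_dx_date, patient_id)
  keep <- abs(as.integer(pr$service_date - anchor[pr$patient_id])) <=
    window_days
  pr <- pr[keep, ]
  pr$site <- ifelse(fac_band[pr$facility_id] == "CP_0_19", "CP", "HP")
  per <- pr %>%
    group_by(.data$patient_id) %>%
    summarise(cp = any(.data$site == "CP"), hp = any(.data$site == "HP"),
              .groups = "drop")
  out <- tibble(patient_id = patient_id) %>%
    left_join(per, by = "patient_id") %>%
    mutate(cp = !is.na(.data$cp) & .data$cp, hp = !is.na(.data$hp) & .data$hp,
           imaging_done = .data$cp | .data$hp,
           imaging_site = dplyr::case_when(
             .data$cp & .data$hp ~ "both",
             .data$cp ~ "CP",
             .data$hp ~ "HP",
             TRUE ~ "none"))
  select(out, "patient_id", "imaging_done", "imaging_site")
}

#' Build the headache cohort
#'
#' Adults (18 or older at index) with at least one headache (R51) or
#' migraine (G43) diagnosis claim — suspected diagnoses count — and at
#' least `baseline_days` of continuous enrollment before the index date.
#' The index date is the first day of the calendar month of the earliest
#' qualifying claim. Follow-up runs from the index date to the last
#' observed visit. Facility band is taken from the facility of the first
#' qualifying claim; imaging is attributed within `imaging_window_days` of
#' that claim's date; baseline comorbidities are flagged over the
#' `baseline_days` window before index.
#'
#' @param bundle A `claims_bundle`.
#' @param baseline_days Required continuous enrollment before index
#'   (default 183, i.e. 6 months).
#' @param min_age Minimum age at index (default 18).
#' @param imaging_window_days Imaging attribution half-window (default 90).
#' @param comorbidity_map See [default_comorbidity_map()].
#' @return Tibble of cohort members (one row per patient) with an
#'   `attrition` attribute: a tibble of exclusion reasons and counts whose
#'   total equals the candidate count.
#' @export
build_headache_cohort <- function(bundle, baseline_days = 183, min_age = 18,
                                  imaging_window_days = 90,
                                  comorbidity_map =
                                    default_comorbidity_map()) {
  dx <- filter(bundle$diagnoses, HEADACHE_ICD(.data$icd10))
  empty <- tibble(
    patient_id = character(), cohort = character(),
    index_date = as.Date(character()), first_dx_date = as.Date(character()),
    age_at_index = integer(), sex = character(), follow_up_days = integer(),
    index_diagnosis = character(), index_facility_band = character(),
    imaging_done = logical(), imaging_site = character())
  if (nrow(dx) == 0) {
    attr(empty, "attrition") <- tibble(reason = character(), n = integer())
    return(empty)
  }
  first_dx <- dx %>%
    arrange(.data$patient_id, .data$service_date, .data$icd10,
            .data$facility_id) %>%
    group_by(.data$patient_id) %>%
    summarise(
      first_dx_date = min(.data$service_date),
      index_facility = dplyr::first(.data$facility_id),
      index_diagnosis = ifelse(
        any(startsWith(.data$icd10[.data$service_date ==
                                     min(.data$service_date)], "G43")),
        "migraine", "headache"),
      .groups = "drop") %>%
    mutate(index_date = month_floor(.data$first_dx_date))

  enr1 <- distinct(bundle$enrollment, .data$patient_id, .keep_all = TRUE)
  cand <- first_dx %>%
    left_join(select(enr1, "patient_id", "birth_year", "sex"),
              by = "patient_id") %>%
    mutate(age_at_index = age_at_date(.data$birth_year, .data$index_date))

  n_cand <- nrow(cand)
  ok_age <- cand$age_at_index >= min_age
  ok_base <- has_baseline_enrollment(bundle$enrollment, cand$patient_id,
                                     cand$index_date, baseline_days)
  # first applicable exclusion reason per candidate
  excluded_age <- sum(!ok_age)
  excluded_baseline <- sum(ok_age & !ok_base)
  members <- cand[ok_age & ok_base, ]

  lv <- last_visit_dates(bundle)
  members <- members %>%
    left_join(lv, by = "patient_id") %>%
    mutate(cohort = "headache",
           follow_up_days = as.integer(.data$last_visit - .data$index_date))

  fac_band <- setNames(classify_facility_band(bundle$facilities$bed_count),
                       bundle$facilities$facility_id)
  members$index_facility_band <- unname(fac_band[members$index_facility])

  img <- attribute_imaging(bundle, members$patient_id, members$first_dx_date,
                           imaging_window_days)
  cm <- flag_baseline_comorbidities(bundle, members$patient_id,
                                    members$index_date, comorbidity_map,
                                    baseline_days)
  out <- members %>%
    select("patient_id", "cohort", "index_date", "first_dx_date",
           "age_at_index", "sex", "follow_up_days", "index_diagnosis",
           "index_facility_band") %>%
    left_join(img, by = "patient_id") %>%
    left_join(cm, by = "patient_id") %>%
    arrange(.data$patient_id)
  attr(out, "attrition") <- tibble(
    reason = c("included", "age_below_minimum", "insufficient_baseline"),
    n = c(nrow(out), excluded_age, excluded_baseline))
  stopifnot(sum(attr(out, "attrition")$n) == n_cand)
  out
}

#' Build the migraine cohort
#'
#' Headache-cohort members with at least one migraine (G43) diagnosis claim
#' and at least one prescription for a migraine treatment (any acute or
#' preventive molecule in the codelist). The index date is the date of the
#' first such prescription — by default no temporal order against the G43
#' claim is imposed; `strict_order = TRUE` restricts to prescriptions on or
#' after the first day of the month of the first G43 claim. Patients with a
#' confirmed (non-suspected) cluster-headache (G44.0) diagnosis are
#' excluded. Follow-up, age and baseline comorbidities are re-anchored at
#' the migraine index.
#'
#' @param bundle A `claims_bundle`.
#' @param headache_cohort Output of [build_headache_cohort()].
#' @param codelist Codelist tibble.
#' @param strict_order Require the index prescription not to precede the
#'   first G43 month (default `FALSE`).
#' @param baseline_days Baseline window for comorbidity flags (default 183).
#' @param comorbidity_map See [default_comorbidity_map()].
#' @return Tibble of migraine-cohort members with an `attrition` attribute.
#' @export
build_migraine_cohort <- function(bundle, headache_cohort,
                                  codelist = default_codelist(),
                                  strict_order = FALSE, baseline_days = 183,
                                  comorbidity_map =
                                    default_comorbidity_map()) {
  g43 <- bundle$diagnoses %>%
    filter(startsWith(.data$icd10, "G43"),
           .data$patient_id %in% headache_cohort$patient_id) %>%
    group_by(.data$patient_id) %>%
    summarise(first_g43 = min(.data$service_date), .groups = "drop")

  cls <- classify_molecule(bundle$prescriptions$molecule, codelist)
  rx <- bundle$prescriptions %>%
    mutate(treatment_type = cls$treatment_type) %>%
    filter(.data$treatment_type %in% c("acute", "preventive"),
           .data$patient_id %in% g43$patient_id)
  if (strict_order) {
    rx <- rx %>%
      left_join(g43, by = "patient_id") %>%
      filter(.data$rx_date >= month_floor(.data$first_g43))
  }
  first_rx <- rx %>%
    group_by(.data$patient_id) %>%
    summarise(index_date = min(.data$rx_date), .groups = "drop")

  cluster <- bundle$diagnoses %>%
    filter(.data$icd10 == "G44.0", !.data$suspected) %>%
    pull(.data$patient_id) %>% unique()

  n_cand <- nrow(g43)
  no_treatment <- sum(!g43$patient_id %in% first_rx$patient_id)
  with_rx <- filter(first_rx, TRUE)
  cluster_excluded <- sum(with_rx$patient_id %in% cluster)
  members <- filter(with_rx, !.data$patient_id %in% cluster)

  hc <- headache_cohort %>%
    select("patient_id", "sex", "index_diagnosis", "index_facility_band",
           "imaging_done", "imaging_site")
  enr1 <- distinct(bundle$enrollment, .data$patient_id, .keep_all = TRUE)
  lv <- last_visit_dates(bundle)
  members <- members %>%
    left_join(hc, by = "patient_id") %>%
    left_join(select(enr1, "patient_id", "birth_year"), by = "patient_id") %>%
    left_join(lv, by = "patient_id") %>%
    mutate(cohort = "migraine",
           age_at_index = age_at_date(.data$birth_year, .data$index_date),
           follow_up_days = as.integer(.data$last_visit - .data$index_date))
  cm <- flag_baseline_comorbidities(bundle, members$patient_id,
                                    members$index_date, comorbidity_map,
                                    baseline_days)
  out <- members %>%
    select("patient_id", "cohort", "index_date", "age_at_index", "sex",
           "follow_up_days", "index_diagnosis", "index_facility_band",
           "imaging_done", "imaging_site") %>%
    left_join(cm, by = "patient_id") %>%
    arrange(.data$patient_id)
  attr(out, "attrition") <- tibble(
    reason = c("included", "no_migraine_treatment",
               "confirmed_cluster_headache"),
    n = c(nrow(out), no_treatment, cluster_excluded))
  stopifnot(sum(attr(out, "attrition")$n) == n_cand)
  out
}

#' Select the 12-month follow-up population
#'
#' Members of a cohort whose follow-up (index date to last visit) is at
#' least `min_days` days; 365 days counts as 12 months (inclusive
#' boundary).
#'
#' @param cohort A cohort tibble.
#' @param min_days Minimum follow-up in days (default 365).
#' @return The qualifying subset of the cohort.
#' @export
select_12m_population <- function(cohort, min_days = 365) {
  filter(cohort, .data$follow_up_days >= min_days)
}
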