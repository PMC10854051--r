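# Output surfaces: percentage convention, yearly treatment trends,
# ever-use treatment summary, and the end-to-end pipeline runner.

#' Percentage, one decimal, half-up
#'
#' The printing convention used in every emitted table: `100 * n / d`
#' rounded half-up to one decimal place. Counts are never rounded.
#'
#' @param numerator,denominator Non-negative counts (vectorized;
#'   `denominator` recycles).
#' @return Numeric percentage(s) with one decimal.
#' @export
pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(numerator < 0)) stop("numerator must be >= 0", call. = FALSE)
  floor(1000 * numerator / denominator + 0.5) / 10
}

#' Yearly trend of acute and preventive treatment
#'
#' A patient contributes to calendar year Y when they have at least one
#' migraine-treatment prescription dated in Y (prevalent-year counting, by
#' prescription date rather than index year). Within each year, the acute
#' and preventive percentages are the share of that year's contributors
#' with at least one acute / preventive prescription in the year, and
#' likewise per drug class.
#'
#' @param cohort Migraine cohort tibble (defines the patient universe).
#' @param prescriptions Prescription claims tibble.
#' @param codelist Codelist tibble.
#' @return Tibble with `year`, `n_patients`, `pct_acute`, `pct_preventive`
#'   and one `pct_<class>` column per drug class; empty cohort yields an
#'   empty tibble.
#' @export
yearly_trend <- function(cohort, prescriptions,
                         codelist = default_codelist()) {
  all_classes <- c(ACUTE_CLASSES, PREVENTIVE_CLASSES)
  empty <- tibble(year = integer(), n_patients = integer(),
                  pct_acute = numeric(), pct_preventive = numeric())
  for (cl in all_classes) empty[[paste0("pct_", cl)]] <- numeric()
  if (nrow(cohort) == 0) return(empty)
  cls <- classify_molecule(prescriptions$molecule, codelist)
  rx <- prescriptions %>%
    mutate(drug_class = cls$drug_class,
           treatment_type = cls$treatment_type) %>%
    filter(.data$treatment_type %in% c("acute", "preventive"),
           .data$patient_id %in% cohort$patient_id) %>%
    mutate(year = as.integer(format(.data$rx_date, "%Y")))
  if (nrow(rx) == 0) return(empty)
  pieces <- lapply(sort(unique(rx$year)), function(y) {
    ry <- filter(rx, .data$year == y)
    ids <- unique(ry$patient_id)
    den <- length(ids)
    row <- tibble(
      year = y, n_patients = den,
      pct_acute = pct(dplyr::n_distinct(
        ry$patient_id[ry$treatment_type == "acute"]), den),
      pct_preventive = pct(dplyr::n_distinct(
        ry$patient_id[ry$treatment_type == "preventive"]), den))
    for (cl in all_classes) {
      row[[paste0("pct_", cl)]] <- pct(dplyr::n_distinct(
        ry$patient_id[ry$drug_class == cl]), den)
    }
    row
  })
  bind_rows(pieces)
}

#' Ever-use treatment summary over follow-up
#'
#' Per-patient ever-use flags over the whole follow-up: counts and
#' percentages of the cohort receiving any acute treatment, any preventive
#' treatment, acute only, preventive only, both, and each drug class (and
#' molecule when molecule-level episodes are supplied). The acute-only /
#' preventive-only / both groups partition the treated patients.
#'
#' @param cohort Migraine cohort tibble (denominator).
#' @param class_episodes Class-level episodes for the cohort's patients.
#' @param molecule_episodes Optional molecule-level episodes for per-
#'   molecule counts.
#' @return Tibble with `label`, `n`, `pct` (percentages of the cohort
#'   size).
#' @export
treatment_received_summary <- function(cohort, class_episodes,
                                       molecule_episodes = NULL) {
  den <- nrow(cohort)
  if (den == 0) return(tibble(label = character(), n = integer(),
                              pct = numeric()))
  ep <- filter(class_episodes, .data$patient_id %in% cohort$patient_id)
  acute_ids <- unique(ep$patient_id[ep$drug_class %in% ACUTE_CLASSES])
  prev_ids <- unique(ep$patient_id[ep$drug_class %in% PREVENTIVE_CLASSES])
  rows <- list(
    tibble(label = "any_acute", n = length(acute_ids)),
    tibble(label = "any_preventive", n = length(prev_ids)),
    tibble(label = "acute_only", n = length(setdiff(acute_ids, prev_ids))),
    tibble(label = "preventive_only",
           n = length(setdiff(prev_ids, acute_ids))),
    tibble(label = "both_acute_and_preventive",
           n = length(intersect(acute_ids, prev_ids))))
  for (cl in c(ACUTE_CLASSES, PREVENTIVE_CLASSES)) {
    rows[[length(rows) + 1]] <- tibble(
      label = cl, n = dplyr::n_distinct(ep$patient_id[ep$drug_class == cl]))
  }
  if (!is.null(molecule_episodes)) {
    me <- filter(molecule_episodes,
                 .data$patient_id %in% cohort$patient_id)
    for (mol in sort(unique(me$key))) {
      rows[[length(rows) + 1]] <- tibble(
        label = paste0("molecule_", mol),
        n = dplyr::n_distinct(me$patient_id[me$key == mol]))
    }
  }
  out <- bind_rows(rows)
  mutate(out, pct = pct(.data$n, den))
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its default:
#' baseline window 183 days, minimum age 18, imaging half-window 90 days,
#' refill gap 60 days, line grace window 30 days, at most 4 lines,
#' 12-month follow-up = 365 days, ICHD-3 MOH thresholds, 90-day preventive
#' continuation and 3-month before/after windows for Case 3.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    baseline_days = 183, min_age = 18, imaging_window_days = 90,
    gap_days = 60, grace_days = 30, max_lines = 4, followup_12m_days = 365,
    moh = moh_thresholds(), switch_window_days = 60,
    continuation_days = 90, window_months = 3, strict_order = FALSE)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full claims analysis pipeline
#'
#' Executes cohorts, episodes, lines, case phenotyping and every summary
#' table, returning all intermediate and final objects and optionally
#' writing them as CSVs plus a run-metadata YAML. The run is deterministic
#' given identical inputs.
#'
#' @param bundle A `claims_bundle` (loaded or simulated).
#' @param config A [pipeline_config()] list.
#' @param out_dir Optional output directory; when given, all tables are
#'   written there.
#' @return A named list: `headache_cohort`, `migraine_cohort`,
#'   `population_12m`, `molecule_episodes`, `class_episodes`,
#'   `monthly_exposure`, `lines`, `case_flags`, `table1`, `table2`,
#'   `table3`, `table4`, `trend`, `treatment_summary`,
#'   `prescription_periods`, `attrition`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  codelist <- bundle$codelist
  hc <- stage("headache_cohort", build_headache_cohort(
    bundle, config$baseline_days, config$min_age,
    config$imaging_window_days))
  mc <- stage("migraine_cohort", build_migraine_cohort(
    bundle, hc, codelist, config$strict_order, config$baseline_days))
  pop12 <- select_12m_population(mc, config$followup_12m_days)

  rx_mc <- filter(bundle$prescriptions,
                  .data$patient_id %in% mc$patient_id)
  mol_ep <- stage("episodes", chain_episodes(
    rx_mc, codelist, "molecule", config$gap_days))
  cls_ep <- chain_episodes(rx_mc, codelist, "class", config$gap_days)
  expo <- monthly_acute_days(rx_mc, codelist)

  idx <- setNames(mc$index_date, mc$patient_id)
  lines <- stage("lines", assign_lines(cls_ep, config$grace_days,
                                       config$max_lines, idx))
  flags <- stage("cases", compute_case_flags(
    pop12$patient_id, mol_ep, cls_ep, expo, config$moh,
    config$switch_window_days, config$continuation_days,
    config$window_months))

  preventive_users <- unique(
    cls_ep$patient_id[cls_ep$drug_class %in% PREVENTIVE_CLASSES])
  table1 <- stage("table1", cohort_characteristics_table(list(
    headache = hc, migraine = mc)))
  table2 <- stage("table2", facility_imaging_table(hc))
  table3 <- line_summary_table(lines)
  table4 <- stage("table4", case_summary(flags, pop12, preventive_users))
  trend <- yearly_trend(mc, bundle$prescriptions, codelist)
  treat <- treatment_received_summary(mc, cls_ep, mol_ep)
  periods <- summarize_prescription_periods(cls_ep)
  attrition <- bind_rows(
    mutate(attr(hc, "attrition"), cohort = "headache"),
    mutate(attr(mc, "attrition"), cohort = "migraine"))

  res <- list(headache_cohort = hc, migraine_cohort = mc,
              population_12m = pop12, molecule_episodes = mol_ep,
              class_episodes = cls_ep, monthly_exposure = expo,
              lines = lines, case_flags = flags, table1 = table1,
              table2 = table2, table3 = table3, table4 = table4,
              trend = trend, treatment_summary = treat,
              prescription_periods = periods, attrition = attrition)
  if (!is.null(out_dir)) write_pipeline_outputs(res, config, out_dir)
  res
}

#' Cohort demographics and comorbidity table
#'
#' Count/percentage and mean/SD rows per cohort: size, age, sex,
#' follow-up duration in months (days / 30.4375), index diagnosis and each
#' baseline comorbidity group.
#'
#' @param cohorts Named list of cohort tibbles.
#' @return Long tibble with `cohort`, `label`, `n`, `pct`, `mean`, `sd`.
#' @export
cohort_characteristics_table <- function(cohorts) {
  pieces <- lapply(names(cohorts), function(nm) {
    d <- cohorts[[nm]]
    den <- nrow(d)
    if (den == 0) return(NULL)
    rows <- list(
      tibble(label = "n_patients", n = den, pct = NA_real_,
             mean = NA_real_, sd = NA_real_),
      tibble(label = "age_years", n = NA_integer_, pct = NA_real_,
             mean = mean(d$age_at_index), sd = stats::sd(d$age_at_index)),
      tibble(label = "female", n = sum(d$sex == "female"),
             pct = pct(sum(d$sex == "female"), den),
             mean = NA_real_, sd = NA_real_),
      tibble(label = "male", n = sum(d$sex == "male"),
             pct = pct(sum(d$sex == "male"), den),
             mean = NA_real_, sd = NA_real_),
      tibble(label = "follow_up_months", n = NA_integer_, pct = NA_real_,
             mean = mean(d$follow_up_days / 30.4375),
             sd = stats::sd(d$follow_up_days / 30.4375)))
    for (dg in c("headache", "migraine")) {
      rows[[length(rows) + 1]] <- tibble(
        label = paste0("index_diagnosis_", dg),
        n = sum(d$index_diagnosis == dg),
        pct = pct(sum(d$index_diagnosis == dg), den),
        mean = NA_real_, sd = NA_real_)
    }
    for (cc in grep("^cm_", names(d), value = TRUE)) {
      rows[[length(rows) + 1]] <- tibble(
        label = cc, n = sum(d[[cc]]), pct = pct(sum(d[[cc]]), den),
        mean = NA_real_, sd = NA_real_)
    }
    mutate(bind_rows(rows), cohort = nm)
  })
  select(bind_rows(pieces), "cohort", "label", "n", "pct", "mean", "sd")
}

#' Facility-band and imaging table for the headache cohort
#'
#' Counts and percentages per bed-count band, plus imaging status overall
#' and split by whether the index facility was a clinic (CP) or hospital
#' (HP) — the imaging percentage within each split uses that split's
#' patient count as denominator.
#'
#' @param headache_cohort Output of [build_headache_cohort()].
#' @return Tibble with `label`, `n`, `denominator`, `pct`.
#' @export
facility_imaging_table <- function(headache_cohort) {
  d <- headache_cohort
  den <- nrow(d)
  if (den == 0) return(tibble(label = character(), n = integer(),
                              denominator = integer(), pct = numeric()))
  rows <- lapply(FACILITY_BANDS, function(b) {
    tibble(label = paste0("band_", b),
           n = sum(d$index_facility_band == b), denominator = den,
           pct = pct(sum(d$index_facility_band == b), den))
  })
  cp <- d$index_facility_band == "CP_0_19"
  rows <- c(rows, list(
    tibble(label = "imaging_total", n = sum(d$imaging_done),
           denominator = den, pct = pct(sum(d$imaging_done), den)),
    tibble(label = "imaging_at_cp_index", n = sum(d$imaging_done & cp),
           denominator = sum(cp),
           pct = if (any(cp)) pct(sum(d$imaging_done & cp), sum(cp))
                 else NA_real_),
    tibble(label = "imaging_at_hp_index", n = sum(d$imaging_done & !cp),
           denominator = sum(!cp),
           pct = if (any(!cp)) pct(sum(d$imaging_done & !cp), sum(!cp))
                 else NA_real_)))
  bind_rows(rows)
}

write_pipeline_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name) {
    df <- as.data.frame(obj)
    for (cc in names(df)) {
      if (inherits(df[[cc]], "Date")) df[[cc]] <- format_iso_date(df[[cc]])
    }
    write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wr(res$headache_cohort, "headache_cohort.csv")
  wr(res$migraine_cohort, "migraine_cohort.csv")
  wr(res$molecule_episodes, "episodes_molecule.csv")
  wr(res$class_episodes, "episodes_class.csv")
  wr(res$lines, "lines.csv")
  wr(res$case_flags, "cases.csv")
  wr(res$table1, "table1.csv")
  wr(res$table2, "table2.csv")
  wr(res$table3, "table3.csv")
  wr(res$table4, "table4.csv")
  wr(res$trend, "trend.csv")
  wr(res$treatment_summary, "treatment_summary.csv")
  wr(res$prescription_periods, "prescription_periods.csv")
  wr(res$attrition, "attrition.csv")
  meta <- list(
    package = "migrainepaths",
    version = as.character(utils::packageVersion("migrainepaths")),
    config = config,
    counts = list(
      headache_cohort = nrow(res$headache_cohort),
      migraine_cohort = nrow(res$migraine_cohort),
      population_12m = nrow(res$population_12m)))
  yaml::write_yaml(meta, file.path(out_dir, "run_meta.yaml"))
  invisible(out_dir)
}
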