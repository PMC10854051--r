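# Hand-built fixture bundles, constructed in code.

d <- function(x) as.Date(x)

# Assemble a bundle from partial tables, filling the rest with empty
# schema-conformant tibbles and a two-facility registry (one clinic, one
# large hospital).
toy_bundle <- function(enrollment = NULL, diagnoses = NULL,
                       prescriptions = NULL, procedures = NULL,
                       facilities = NULL, codelist = default_codelist()) {
  b <- list(
    enrollment = enrollment %||% tibble::tibble(
      patient_id = character(), birth_year = integer(), sex = character(),
      start_date = as.Date(character()), end_date = as.Date(character())),
    diagnoses = diagnoses %||% tibble::tibble(
      patient_id = character(), service_date = as.Date(character()),
      icd10 = character(), suspected = logical(), facility_id = character()),
    prescriptions = prescriptions %||% tibble::tibble(
      patient_id = character(), rx_date = as.Date(character()),
      molecule = character(), days_supplied = integer()),
    procedures = procedures %||% tibble::tibble(
      patient_id = character(), service_date = as.Date(character()),
      modality = character(), facility_id = character()),
    facilities = facilities %||% tibble::tibble(
      facility_id = c("FCP", "FHP"), bed_count = c(10L, 520L)),
    codelist = codelist)
  class(b) <- "claims_bundle"
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

enr_row <- function(pid, birth_year = 1985, sex = "female",
                    start = "2018-01-01", end = NA) {
  tibble::tibble(patient_id = pid, birth_year = as.integer(birth_year),
                 sex = sex, start_date = d(start),
                 end_date = if (is.na(end)) as.Date(NA) else d(end))
}

dx_row <- function(pid, date, icd10 = "R51", suspected = FALSE,
                   facility = "FCP") {
  tibble::tibble(patient_id = pid, service_date = d(date), icd10 = icd10,
                 suspected = suspected, facility_id = facility)
}

rx_row <- function(pid, date, molecule = "loxoprofen", days = 10L) {
  tibble::tibble(patient_id = pid, rx_date = d(date), molecule = molecule,
                 days_supplied = as.integer(days))
}

pr_row <- function(pid, date, modality = "CT", facility = "FCP") {
  tibble::tibble(patient_id = pid, service_date = d(date),
                 modality = modality, facility_id = facility)
}

# Three-patient fixture: one headache-only patient, one migraine patient
# with treatment, one patient with neither.
fixture_bundle <- function() {
  toy_bundle(
    enrollment = dplyr::bind_rows(
      enr_row("P1", birth_year = 1989),
      enr_row("P2", birth_year = 1980, sex = "male"),
      enr_row("P3", birth_year = 1975)),
    diagnoses = dplyr::bind_rows(
      dx_row("P1", "2019-03-17", "R51", facility = "FCP"),
      dx_row("P1", "2019-06-01", "R51", facility = "FCP"),
      dx_row("P2", "2020-05-01", "G43", facility = "FHP"),
      dx_row("P2", "2021-06-15", "G43", facility = "FHP"),
      dx_row("P3", "2019-02-01", "J06", facility = "FCP")),
    prescriptions = dplyr::bind_rows(
      rx_row("P2", "2020-05-10", "rizatriptan", 10),
      rx_row("P2", "2020-07-01", "rizatriptan", 10)),
    procedures = pr_row("P2", "2020-05-20", "CT", facility = "FHP"))
}

# Shared simulation at the scale used for parameter recovery; built once
# per test run.
.shared <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_bundle(sim_config(n_patients = 4000, seed = 101))
  }
  .shared$sim
}

shared_pipeline <- function() {
  if (is.null(.shared$res)) {
    .shared$res <- run_pipeline(shared_sim()$bundle)
  }
  .shared$res
}
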