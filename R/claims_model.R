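#' @importFrom dplyr %>% .data arrange bind_rows count distinct filter
#'   group_by left_join mutate n pull rename select summarise ungroup
#' @importFrom rlang .env
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rbinom rnorm runif setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Default drug codelist
#'
#' Maps each drug molecule to its class and treatment type (acute or
#' preventive). Acute classes are acetaminophen/NSAIDs, triptans and
#' ergotamine; preventive classes are anti-CGRP monoclonal antibodies,
#' antiepileptics, antidepressants, beta-blockers and calcium-channel
#' blockers, the set of drug classes approved for migraine in Japan. The
#' default list covers the commonly prescribed molecules per class and can be
#' replaced by any table with the same three columns.
#'
#' @return A tibble with columns `molecule`, `drug_class`, `treatment_type`.
#' @export
default_codelist <- function() {
  tibble(
    molecule = c(
      "loxoprofen", "acetaminophen", "ibuprofen", "naproxen", "diclofenac",
      "celecoxib",
      "rizatriptan", "sumatriptan", "eletriptan", "zolmitriptan",
      "naratriptan",
      "ergotamine", "dihydroergotamine",
      "galcanezumab", "erenumab", "fremanezumab",
      "valproate", "topiramate",
      "amitriptyline",
      "propranolol",
      "lomerizine", "verapamil"
    ),
    drug_class = c(
      rep("acetaminophen_nsaid", 6),
      rep("triptan", 5),
      rep("ergotamine", 2),
      rep("anti_cgrp_mab", 3),
      rep("antiepileptic", 2),
      "antidepressant",
      "beta_blocker",
      rep("ca_channel_blocker", 2)
    ),
    treatment_type = c(rep("acute", 13), rep("preventive", 9))
  )
}

#' Default comorbidity map
#'
#' ICD-10 prefix blocks for the twelve baseline comorbidity groups reported
#' for headache/migraine cohorts. The groups are standard ICD-10 chapter
#' blocks: cerebrovascular disease I60-I69, hypertension I10-I15, ischemic
#' heart disease I20-I25, peripheral vascular disease I70-I79, brain
#' malignancy C71, other malignancy C00-C97 excluding C71, meningitis
#' G00-G03, mood disorders F30-F39, neurotic/stress-related/somatoform
#' disorders F40-F48, epilepsy G40-G41, thyroid disorders E00-E07 and
#' diabetes mellitus E10-E14. Each entry lists the code prefixes that match
#' (a claim matches a group if its code starts with any included prefix and
#' no excluded prefix).
#'
#' @return Named list of lists with elements `include` and `exclude`
#'   (character vectors of ICD-10 prefixes).
#' @export
default_comorbidity_map <- function() {
  rng <- function(letter, from, to) sprintf("%s%02d", letter, from:to)
  list(
    cerebrovascular_disease       = list(include = rng("I", 60, 69), exclude = character()),
    hypertension                  = list(include = rng("I", 10, 15), exclude = character()),
    ischemic_heart_disease        = list(include = rng("I", 20, 25), exclude = character()),
    peripheral_vascular_disease   = list(include = rng("I", 70, 79), exclude = character()),
    brain_malignancy              = list(include = "C71",            exclude = character()),
    other_malignancy              = list(include = rng("C", 0, 97),  exclude = "C71"),
    meningitis                    = list(include = rng("G", 0, 3),   exclude = character()),
    mood_disorders                = list(include = rng("F", 30, 39), exclude = character()),
    neurotic_stress_somatoform    = list(include = rng("F", 40, 48), exclude = character()),
    epilepsy                      = list(include = rng("G", 40, 41), exclude = character()),
    thyroid_disorders             = list(include = rng("E", 0, 7),   exclude = character()),
    diabetes_mellitus             = list(include = rng("E", 10, 14), exclude = character())
  )
}

#' Classify a molecule into drug class and treatment type
#'
#' Deterministic lookup against a codelist. Molecules absent from the
#' codelist are classed `"other"` with treatment type `"neither"` and a
#' warning; such prescriptions are excluded from all migraine-treatment
#' logic downstream.
#'
#' @param molecule Character vector of molecule names.
#' @param codelist Codelist tibble (see [default_codelist()]).
#' @return A tibble with columns `molecule`, `drug_class`, `treatment_type`,
#'   one row per input element.
#' @export
classify_molecule <- function(molecule, codelist = default_codelist()) {
  idx <- match(molecule, codelist$molecule)
  unknown <- unique(molecule[is.na(idx)])
  if (length(unknown) > 0) {
    warning("unknown molecule(s), classed as 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  tibble(
    molecule = molecule,
    drug_class = ifelse(is.na(idx), "other", codelist$drug_class[idx]),
    treatment_type = ifelse(is.na(idx), "neither",
                            codelist$treatment_type[idx])
  )
}

# ---- CSV schemas -----------------------------------------------------------

BUNDLE_SCHEMAS <- list(
  enrollment    = c("patient_id", "birth_year", "sex", "start_date", "end_date"),
  diagnoses     = c("patient_id", "service_date", "icd10", "suspected", "facility_id"),
  prescriptions = c("patient_id", "rx_date", "molecule", "days_supplied"),
  procedures    = c("patient_id", "service_date", "modality", "facility_id"),
  facilities    = c("facility_id", "bed_count"),
  codelist      = c("molecule", "drug_class", "treatment_type")
)

parse_iso_date <- function(x, file, column) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonblank <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[nonblank], format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    bad <- which(nonblank)[which(is.na(parsed))[1]]
    stop(sprintf("%s: row %d, column '%s': invalid ISO date '%s'",
                 file, bad, column, x[bad]), call. = FALSE)
  }
  out[nonblank] <- parsed
  out
}

read_bundle_table <- function(path, table) {
  cols <- BUNDLE_SCHEMAS[[table]]
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), cols)) {
    stop(sprintf("%s: expected columns [%s], found [%s]",
                 path, paste(cols, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  df <- as_tibble(df)
  fname <- basename(path)
  switch(table,
    enrollment = mutate(df,
      birth_year = as.integer(.data$birth_year),
      start_date = parse_iso_date(.data$start_date, fname, "start_date"),
      end_date   = parse_iso_date(.data$end_date, fname, "end_date")),
    diagnoses = mutate(df,
      service_date = parse_iso_date(.data$service_date, fname, "service_date"),
      suspected = as.integer(.data$suspected) == 1L),
    prescriptions = mutate(df,
      rx_date = parse_iso_date(.data$rx_date, fname, "rx_date"),
      days_supplied = as.integer(.data$days_supplied)),
    procedures = mutate(df,
      service_date = parse_iso_date(.data$service_date, fname, "service_date")),
    facilities = mutate(df, bed_count = as.integer(.data$bed_count)),
    codelist = df
  )
}

#' Load a claims bundle from CSV files
#'
#' Reads the five claims tables plus the drug codelist, coerces types
#' (ISO-8601 dates, integer day counts, 0/1 suspected flag) and validates
#' cross-table referential integrity: every facility referenced by a
#' diagnosis or procedure claim must exist in the facility registry and
#' every prescribed molecule must be resolvable through the codelist.
#'
#' @param dir Directory containing `enrollment.csv`, `diagnoses.csv`,
#'   `prescriptions.csv`, `procedures.csv`, `facilities.csv` and (unless
#'   `codelist` is given) `codelist.csv`.
#' @param codelist Optional codelist tibble overriding `codelist.csv`.
#' @return A `claims_bundle`: a list of the six tibbles.
#' @export
load_claims_bundle <- function(dir, codelist = NULL) {
  tables <- setdiff(names(BUNDLE_SCHEMAS), "codelist")
  paths <- file.path(dir, paste0(tables, ".csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing bundle file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bundle <- setNames(lapply(seq_along(tables), function(i) {
    read_bundle_table(paths[i], tables[i])
  }), tables)
  if (is.null(codelist)) {
    cl_path <- file.path(dir, "codelist.csv")
    codelist <- if (file.exists(cl_path)) {
      read_bundle_table(cl_path, "codelist")
    } else {
      default_codelist()
    }
  }
  bundle$codelist <- as_tibble(codelist)
  class(bundle) <- "claims_bundle"
  validate_claims_bundle(bundle)
  bundle
}

#' Validate claims-bundle invariants
#'
#' Checks the structural invariants of a bundle: positive supply days,
#' well-formed ICD-10 codes, non-overlapping enrollment spans per patient,
#' resolvable facility ids, diagnosis dates covered by an enrollment span,
#' and molecules present in the codelist. The first violation found raises
#' an error naming the table, row and column.
#'
#' @param bundle A `claims_bundle`.
#' @return The bundle, invisibly, if valid.
#' @export
validate_claims_bundle <- function(bundle) {
  enr <- bundle$enrollment
  if (any(!nzchar(enr$patient_id))) {
    stop("enrollment: empty patient_id", call. = FALSE)
  }
  bad_sex <- which(!enr$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    stop(sprintf("enrollment: row %d, column 'sex': invalid value '%s'",
                 bad_sex[1], enr$sex[bad_sex[1]]), call. = FALSE)
  }
  bad_span <- which(!is.na(enr$end_date) & enr$end_date < enr$start_date)
  if (length(bad_span) > 0) {
    stop(sprintf("enrollment: row %d: end_date before start_date",
                 bad_span[1]), call. = FALSE)
  }
  # non-overlapping spans per patient (open end = unbounded)
  if (nrow(enr) > 1) {
    ord <- order(enr$patient_id, enr$start_date)
    e <- enr[ord, ]
    same <- e$patient_id[-1] == e$patient_id[-nrow(e)]
    prev_end <- e$end_date[-nrow(e)]
    overlap <- same & (is.na(prev_end) | e$start_date[-1] <= prev_end)
    if (any(overlap)) {
      stop(sprintf("enrollment: overlapping spans for patient '%s'",
                   e$patient_id[-1][which(overlap)[1]]), call. = FALSE)
    }
  }

  dx <- bundle$diagnoses
  bad_icd <- which(!grepl("^[A-Z][0-9]{2}(\\.[0-9])?$", dx$icd10))
  if (length(bad_icd) > 0) {
    stop(sprintf("diagnoses: row %d, column 'icd10': malformed code '%s'",
                 bad_icd[1], dx$icd10[bad_icd[1]]), call. = FALSE)
  }
  # every diagnosis inside some enrollment span of the patient
  if (nrow(dx) > 0) {
    enr_split <- split(seq_len(nrow(enr)), enr$patient_id)
    dx_split <- split(seq_len(nrow(dx)), dx$patient_id)
    covered <- rep(FALSE, nrow(dx))
    for (pid in names(dx_split)) {
      if (is.null(enr_split[[pid]])) next
      rows <- dx_split[[pid]]
      sp <- enr[enr_split[[pid]], ]
      for (i in rows) {
        covered[i] <- any(sp$start_date <= dx$service_date[i] &
                            (is.na(sp$end_date) |
                               dx$service_date[i] <= sp$end_date))
      }
    }
    if (any(!covered)) {
      i <- which(!covered)[1]
      stop(sprintf(
        "diagnoses: row %d: service_date outside enrollment for patient '%s'",
        i, dx$patient_id[i]), call. = FALSE)
    }
  }

  rx <- bundle$prescriptions
  bad_days <- which(is.na(rx$days_supplied) | rx$days_supplied < 1L)
  if (length(bad_days) > 0) {
    stop(sprintf(
      "prescriptions: row %d, column 'days_supplied': must be >= 1",
      bad_days[1]), call. = FALSE)
  }
  unknown <- setdiff(unique(rx$molecule), bundle$codelist$molecule)
  if (length(unknown) > 0) {
    stop("prescriptions: molecule(s) not in codelist: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  pr <- bundle$procedures
  bad_mod <- which(!pr$modality %in% c("CT", "MRI"))
  if (length(bad_mod) > 0) {
    stop(sprintf("procedures: row %d, column 'modality': invalid value '%s'",
                 bad_mod[1], pr$modality[bad_mod[1]]), call. = FALSE)
  }

  fac <- bundle$facilities
  if (any(is.na(fac$bed_count) | fac$bed_count < 0L)) {
    stop("facilities: bed_count must be a non-negative integer",
         call. = FALSE)
  }
  if (anyDuplicated(fac$facility_id)) {
    stop("facilities: duplicate facility_id", call. = FALSE)
  }
  ref <- unique(c(dx$facility_id, pr$facility_id))
  unresolved <- setdiff(ref, fac$facility_id)
  if (length(unresolved) > 0) {
    stop("unresolvable facility_id(s): ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }

  cl <- bundle$codelist
  if (anyDuplicated(cl$molecule)) {
    stop("codelist: duplicate molecule", call. = FALSE)
  }
  bad_cl <- which(!(cl$drug_class %in% ACUTE_CLASSES &
                      cl$treatment_type == "acute" |
                    cl$drug_class %in% PREVENTIVE_CLASSES &
                      cl$treatment_type == "preventive" |
                    cl$drug_class == "other"))
  if (length(bad_cl) > 0) {
    stop(sprintf("codelist: row %d: class '%s' inconsistent with type '%s'",
                 bad_cl[1], cl$drug_class[bad_cl[1]],
                 cl$treatment_type[bad_cl[1]]), call. = FALSE)
  }
  invisible(bundle)
}

format_iso_date <- function(x) {
  out <- character(length(x))
  out[!is.na(x)] <- format(x[!is.na(x)], "%Y-%m-%d")
  out
}

#' Write a claims bundle to CSV files
#'
#' Writes the six bundle tables in canonical form: fixed column order,
#' ISO-8601 dates, suspected flag encoded 0/1, no quoting. Loading and
#' re-writing a canonical-form bundle reproduces the files byte-identically.
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_claims_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- list(
    enrollment = function(d) mutate(d,
      start_date = format_iso_date(.data$start_date),
      end_date = format_iso_date(.data$end_date)),
    diagnoses = function(d) mutate(d,
      service_date = format_iso_date(.data$service_date),
      suspected = as.integer(.data$suspected)),
    prescriptions = function(d) mutate(d,
      rx_date = format_iso_date(.data$rx_date)),
    procedures = function(d) mutate(d,
      service_date = format_iso_date(.data$service_date)),
    facilities = identity,
    codelist = identity
  )
  paths <- vapply(names(BUNDLE_SCHEMAS), function(tb) {
    path <- file.path(dir, paste0(tb, ".csv"))
    write.csv(fmt[[tb]](bundle[[tb]]), path, row.names = FALSE,
              quote = FALSE, na = "")
    path
  }, character(1))
  invisible(paths)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (tb in setdiff(names(BUNDLE_SCHEMAS), "codelist")) {
    cat(sprintf("  %-13s %d rows\n", tb, nrow(x[[tb]])))
  }
  cat(sprintf("  codelist      %d molecules\n", nrow(x$codelist)))
  invisible(x)
}
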