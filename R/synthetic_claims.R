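# Seeded synthetic claims generator. Two-layer design: first sample each
# patient's archetype (no headache / headache only / migraine, with planted
# phenotype sub-labels), then emit claims that satisfy the archetype by
# construction, so every downstream detector has exact ground truth. Planted
# positives are built above the detector thresholds and planted negatives
# strictly below them.

# integer uniform on [a, b]; avoids sample()'s length-1 surprise
rint <- function(a, b) a + floor(runif(1) * (b - a + 1))
rdate <- function(from, to) from + rint(0, as.integer(to - from))

TRIPTAN_POOL <- c("rizatriptan", "sumatriptan", "eletriptan")
TRIPTAN_W <- c(0.40, 0.35, 0.25)
NSAID_POOL <- c("loxoprofen", "acetaminophen", "ibuprofen")
NSAID_W <- c(0.50, 0.35, 0.15)
CONV_PREV_POOL <- c("lomerizine", "valproate", "amitriptyline", "propranolol")
CONV_PREV_W <- c(0.60, 0.20, 0.12, 0.08)
NOISE_COMORBID <- c("I10", "I63", "I25", "I73", "F32", "F41", "G40", "E03",
                    "E11", "C50")
NOISE_OTHER <- c("J06", "M54", "K29", "L20")

#' Simulation configuration
#'
#' Parameters of the synthetic claims population. Defaults mirror the
#' marginals of the Japanese claims study the pipeline is designed for:
#' study window 2018-01-01 to 2022-07-31, 56.6% female, age 40 +/- 13
#' years, a 77% clinic share in the facility mix, imaging probabilities of
#' 0.202 at clinics and 0.727 at hospitals, preventive uptake rising from
#' 16.1% (2018) to 26.4% (2022), 69.5% of migraine patients reaching 12
#' months of follow-up, and planted phenotype prevalences among the
#' 12-month population of 1.2% (triptan switch), 3.7% (MOH pattern) and
#' 0.6% (no acute decrease after preventive start).
#'
#' @param n_patients Number of patients.
#' @param study_start,study_end Study window (ISO dates).
#' @param female_fraction Probability of female sex.
#' @param age_mean_sd Mean and SD of age at first diagnosis (years);
#'   sampling is truncated to 19-74 so the adult criterion is met by
#'   construction for non-planted-violator patients.
#' @param p_headache_only,p_migraine Archetype probabilities (the rest of
#'   the population has no headache diagnosis).
#' @param p_cluster_headache Probability that a plain migraine patient
#'   carries a confirmed cluster-headache diagnosis (excluded from the
#'   migraine cohort).
#' @param facility_bed_distribution Weights over the six bed-count bands.
#' @param p_imaging_given_CP,p_imaging_given_HP Imaging probability by
#'   index facility kind.
#' @param refill_gap_range Uniform range (days) between supply exhaustion
#'   and the next refill for background prescriptions.
#' @param planted_prevalences Named vector `p_triptan_switch`,
#'   `p_moh_pattern`, `p_case3_pattern`: phenotype probabilities among
#'   12-month-follow-up migraine patients (mutually exclusive labels).
#' @param p_12m_follow_up Probability that a migraine patient is built with
#'   at least 12 months of follow-up.
#' @param p_preventive_by_year Named vector, year to probability of
#'   background preventive treatment for plain migraine patients.
#' @param p_underage,p_short_baseline Probabilities of planted
#'   cohort-exclusion violators (age below 18; under 6 months of baseline
#'   enrollment) among plain diagnosed patients.
#' @param p_comorbidity_noise,p_other_noise Per-patient probabilities of
#'   background comorbidity / unrelated diagnosis claims.
#' @param seed Integer RNG seed; the generator is fully deterministic
#'   given the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 4000,
                       study_start = "2018-01-01", study_end = "2022-07-31",
                       female_fraction = 0.566, age_mean_sd = c(40.3, 12.9),
                       p_headache_only = 0.40, p_migraine = 0.40,
                       p_cluster_headache = 0.005,
                       facility_bed_distribution = c(
                         CP_0_19 = 0.770, HP_20_99 = 0.047,
                         HP_100_199 = 0.057, HP_200_299 = 0.027,
                         HP_300_499 = 0.061, HP_500_plus = 0.049),
                       p_imaging_given_CP = 0.202,
                       p_imaging_given_HP = 0.727,
                       refill_gap_range = c(0, 45),
                       planted_prevalences = c(p_triptan_switch = 0.012,
                                               p_moh_pattern = 0.037,
                                               p_case3_pattern = 0.006),
                       p_12m_follow_up = 0.695,
                       p_preventive_by_year = c("2018" = 0.161,
                                                "2019" = 0.185,
                                                "2020" = 0.205,
                                                "2021" = 0.230,
                                                "2022" = 0.264),
                       p_underage = 0.02, p_short_baseline = 0.03,
                       p_comorbidity_noise = 0.35, p_other_noise = 0.40,
                       seed = 1) {
  cfg <- list(n_patients = n_patients,
              study_start = as.Date(study_start),
              study_end = as.Date(study_end),
              female_fraction = female_fraction, age_mean_sd = age_mean_sd,
              p_headache_only = p_headache_only, p_migraine = p_migraine,
              p_cluster_headache = p_cluster_headache,
              facility_bed_distribution = facility_bed_distribution /
                sum(facility_bed_distribution),
              p_imaging_given_CP = p_imaging_given_CP,
              p_imaging_given_HP = p_imaging_given_HP,
              refill_gap_range = refill_gap_range,
              planted_prevalences = planted_prevalences,
              p_12m_follow_up = p_12m_follow_up,
              p_preventive_by_year = p_preventive_by_year,
              p_underage = p_underage,
              p_short_baseline = p_short_baseline,
              p_comorbidity_noise = p_comorbidity_noise,
              p_other_noise = p_other_noise, seed = seed)
  probs <- c(cfg$female_fraction, cfg$p_headache_only, cfg$p_migraine,
             cfg$p_cluster_headache, cfg$p_imaging_given_CP,
             cfg$p_imaging_given_HP, cfg$planted_prevalences,
             cfg$p_12m_follow_up, cfg$p_preventive_by_year,
             cfg$p_underage, cfg$p_short_baseline,
             cfg$p_comorbidity_noise, cfg$p_other_noise)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  }
  if (cfg$study_start >= cfg$study_end) {
    stop("study_start must precede study_end", call. = FALSE)
  }
  if (cfg$p_headache_only + cfg$p_migraine > 1) {
    stop("archetype probabilities exceed 1", call. = FALSE)
  }
  if (sum(cfg$planted_prevalences) > 1) {
    stop("planted prevalences exceed 1", call. = FALSE)
  }
  class(cfg) <- c("sim_config", "list")
  cfg
}

# facility registry with at least two facilities per band
make_facilities <- function(cfg) {
  n_fac <- max(12L, cfg$n_patients %/% 40L)
  per_band <- pmax(round(cfg$facility_bed_distribution * n_fac), 2L)
  ranges <- list(CP_0_19 = c(0, 19), HP_20_99 = c(20, 99),
                 HP_100_199 = c(100, 199), HP_200_299 = c(200, 299),
                 HP_300_499 = c(300, 499), HP_500_plus = c(500, 1200))
  rows <- lapply(FACILITY_BANDS, function(b) {
    k <- per_band[[b]]
    tibble(facility_id = character(k),
           bed_count = vapply(seq_len(k), function(i)
             rint(ranges[[b]][1], ranges[[b]][2]), numeric(1)),
           band = b)
  })
  fac <- bind_rows(rows)
  fac$facility_id <- sprintf("F%03d", seq_len(nrow(fac)))
  fac$bed_count <- as.integer(fac$bed_count)
  fac
}

sample_weighted <- function(pool, w) {
  vv <- cumsum(w / sum(w))
  vv[length(vv)] <- 1
  pool[1 + findInterval(runif(1), vv, rightmost.closed = FALSE)]
}

#' Simulate a claims bundle with planted ground truth
#'
#' Generates the five claims tables plus the default codelist, together
#' with per-patient ground-truth labels for every cohort and phenotype the
#' pipeline detects. Planted phenotype patients satisfy the detector
#' definitions by construction: MOH-pattern patients receive triptans on at
#' least 10 days (or analgesics on at least 15 days) in each of at least 3
#' consecutive calendar months; switchers receive a second triptan molecule
#' starting within 60 days of exhausting the first; no-decrease patients
#' continue a preventive class at least 90 days with non-decreasing monthly
#' acute days. Constructed negatives stay strictly below every threshold.
#' The output is deterministic given the configuration (including its
#' seed) and passes all claims-bundle invariants.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `bundle` (a `claims_bundle`) and `truth` (a
#'   tibble with `patient_id`, `archetype`, cohort and phenotype labels and
#'   planted index dates).
#' @export
simulate_bundle <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  empty_truth <- tibble(
    patient_id = character(), archetype = character(),
    in_headache_cohort = logical(), in_migraine_cohort = logical(),
    in_12m_population = logical(), is_triptan_switcher = logical(),
    is_moh_pattern = logical(), is_case3_pattern = logical(),
    case3_group = character(), has_cluster_headache = logical(),
    headache_index = as.Date(character()),
    migraine_index = as.Date(character()))
  fac <- make_facilities(cfg)
  bundle_tables <- list(
    enrollment = tibble(patient_id = character(), birth_year = integer(),
                        sex = character(), start_date = as.Date(character()),
                        end_date = as.Date(character())),
    diagnoses = tibble(patient_id = character(),
                       service_date = as.Date(character()),
                       icd10 = character(), suspected = logical(),
                       facility_id = character()),
    prescriptions = tibble(patient_id = character(),
                           rx_date = as.Date(character()),
                           molecule = character(), days_supplied = integer()),
    procedures = tibble(patient_id = character(),
                        service_date = as.Date(character()),
                        modality = character(), facility_id = character()),
    facilities = select(fac, "facility_id", "bed_count"),
    codelist = default_codelist())
  if (cfg$n_patients == 0) {
    bundle <- bundle_tables
    class(bundle) <- "claims_bundle"
    return(list(bundle = bundle, truth = empty_truth))
  }

  enr_l <- list(); dx_l <- list(); rx_l <- list(); pr_l <- list()
  truth_l <- list()
  prev_years <- as.integer(names(cfg$p_preventive_by_year))

  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%06d", i)
    sex <- if (runif(1) < cfg$female_fraction) "female" else "male"
    u <- runif(1)
    archetype <- if (u < cfg$p_migraine) "migraine"
                 else if (u < cfg$p_migraine + cfg$p_headache_only)
                   "headache_only"
                 else "none"

    band_i <- sample_weighted(FACILITY_BANDS,
                              cfg$facility_bed_distribution)
    fac_i <- fac$facility_id[fac$band == band_i]
    fac_i <- fac_i[rint(1, length(fac_i))]
    is_cp <- band_i == "CP_0_19"

    dx_rows <- NULL; rx_rows <- NULL; pr_rows <- NULL

    if (archetype == "none") {
      start <- rdate(cfg$study_start - 365, cfg$study_end - 200)
      k <- rint(1, 4)
      dates <- start + 10 + cumsum(vapply(seq_len(k), function(j)
        rint(15, 90), numeric(1)))
      dates <- dates[dates <= cfg$study_end]
      if (length(dates) > 0) {
        codes <- vapply(seq_along(dates), function(j)
          sample_weighted(c(NOISE_OTHER, NOISE_COMORBID),
                          rep(1, length(NOISE_OTHER) +
                                length(NOISE_COMORBID))), character(1))
        dx_rows <- tibble(patient_id = pid, service_date = dates,
                          icd10 = codes, suspected = runif(length(dates)) < 0.2,
                          facility_id = fac_i)
      }
      last_claim <- if (length(dates) > 0) max(dates) else start + 30
      age <- max(19, min(74, round(rnorm(1, cfg$age_mean_sd[1],
                                         cfg$age_mean_sd[2]))))
      enr_l[[pid]] <- tibble(
        patient_id = pid,
        birth_year = as.integer(format(start, "%Y")) - age,
        sex = sex, start_date = start,
        end_date = if (runif(1) < 0.8) as.Date(NA) else
          last_claim + rint(10, 90))
      dx_l[[pid]] <- dx_rows
      truth_l[[pid]] <- tibble(
        patient_id = pid, archetype = archetype,
        in_headache_cohort = FALSE, in_migraine_cohort = FALSE,
        in_12m_population = FALSE, is_triptan_switcher = FALSE,
        is_moh_pattern = FALSE, is_case3_pattern = FALSE,
        case3_group = NA_character_, has_cluster_headache = FALSE,
        headache_index = as.Date(NA), migraine_index = as.Date(NA))
      next
    }

    # ---- diagnosed archetypes -------------------------------------------
    migraine <- archetype == "migraine"
    # phenotype sub-label, only for 12-month migraine patients
    is_12m <- migraine && runif(1) < cfg$p_12m_follow_up
    phenotype <- "plain"
    if (is_12m) {
      pp <- cfg$planted_prevalences
      v <- runif(1)
      phenotype <- if (v < pp[["p_triptan_switch"]]) "switch"
        else if (v < pp[["p_triptan_switch"]] + pp[["p_moh_pattern"]]) "moh"
        else if (v < sum(pp)) "case3"
        else "plain"
    }
    plain <- phenotype == "plain"
    cluster <- migraine && plain && runif(1) < cfg$p_cluster_headache
    underage <- plain && !cluster && runif(1) < cfg$p_underage
    short_baseline <- plain && !cluster && !underage &&
      runif(1) < cfg$p_short_baseline
    violator <- underage || short_baseline

    # anchor: date of the first headache/migraine claim (and, for migraine
    # patients, of the first treatment prescription)
    anchor <- if (is_12m && !violator) {
      rdate(cfg$study_start, cfg$study_end - 430)
    } else {
      rdate(cfg$study_start, cfg$study_end - 310)
    }
    m_a <- month_floor(anchor)
    gap_lo <- cfg$refill_gap_range[1]
    gap_hi <- cfg$refill_gap_range[2]

    case3_group <- NA_character_
    if (migraine) {
      if (phenotype == "switch") {
        mols <- TRIPTAN_POOL[order(runif(3))][1:2]
        a_dates <- anchor + c(0, 35, 70)
        a_days <- vapply(1:3, function(j) rint(5, 9), numeric(1))
        a_end <- a_dates[3] + a_days[3]
        b_start <- a_end + rint(max(0, gap_lo), min(45, gap_hi))
        nb <- rint(2, 4)
        b_dates <- b_start + 35 * (seq_len(nb) - 1)
        b_days <- vapply(seq_len(nb), function(j) rint(5, 9), numeric(1))
        rx_rows <- tibble(
          patient_id = pid, rx_date = c(a_dates, b_dates),
          molecule = c(rep(mols[1], 3), rep(mols[2], nb)),
          days_supplied = as.integer(c(a_days, b_days)))
      } else if (phenotype == "moh") {
        analgesic <- runif(1) < 0.4
        mol <- if (analgesic) sample_weighted(NSAID_POOL, NSAID_W)
               else sample_weighted(TRIPTAN_POOL, TRIPTAN_W)
        run_start <- rint(1, 4)
        run_len <- rint(3, 5)
        run_months <- seq(m_a, by = "1 month",
                          length.out = run_start + run_len)
        run_months <- run_months[-seq_len(run_start)]
        run_dates <- run_months + vapply(seq_len(run_len), function(j)
          rint(2, 12), numeric(1))
        run_days <- vapply(seq_len(run_len), function(j)
          if (analgesic) rint(15, 20) else rint(10, 14), numeric(1))
        base_days <- if (analgesic) rint(5, 14) else rint(3, 9)
        rx_rows <- tibble(
          patient_id = pid,
          rx_date = c(anchor, run_dates),
          molecule = mol,
          days_supplied = as.integer(c(base_days, run_days)))
        if (runif(1) < 0.339) {  # preventive, too short to be eligible
          p0 <- max(run_dates) + rint(0, 60)
          np <- rint(1, 2)
          rx_rows <- bind_rows(rx_rows, tibble(
            patient_id = pid, rx_date = p0 + 30 * (seq_len(np) - 1),
            molecule = sample_weighted(CONV_PREV_POOL, CONV_PREV_W),
            days_supplied = 30L))
        }
      } else if (phenotype == "case3") {
        case3_group <- if (runif(1) < 0.8) "conventional" else "anti_cgrp_mab"
        acute_mol <- if (runif(1) < 0.5) sample_weighted(NSAID_POOL, NSAID_W)
                     else sample_weighted(TRIPTAN_POOL, TRIPTAN_W)
        prev_mol <- if (case3_group == "conventional")
          sample_weighted(CONV_PREV_POOL, CONV_PREV_W) else "galcanezumab"
        months <- seq(m_a, by = "1 month", length.out = 6)
        before_dates <- months[1:3] + 9
        p0 <- months[4] + 14
        after_dates <- c(months[4] + 19, months[5] + 9, months[6] + 9)
        acute_days <- rep(6L, 6)
        acute_days[4:6] <- acute_days[4:6] + as.integer(rint(0, 1))
        rx_rows <- tibble(
          patient_id = pid,
          rx_date = c(before_dates, after_dates, p0 + 30 * (0:3)),
          molecule = c(rep(acute_mol, 6), rep(prev_mol, 4)),
          days_supplied = as.integer(c(acute_days, rep(30L, 4))))
        anchor <- min(rx_rows$rx_date)
      } else {
        # plain migraine patient, below every detector threshold
        use_triptan <- runif(1) < 0.5
        mol <- if (use_triptan) sample_weighted(TRIPTAN_POOL, TRIPTAN_W)
               else sample_weighted(NSAID_POOL, NSAID_W)
        k <- if (is_12m) rint(4, 10) else rint(1, 6)
        gaps <- vapply(seq_len(max(0, k - 1)), function(j)
          rint(32, 60), numeric(1))
        dates <- anchor + c(0, cumsum(gaps))
        horizon <- if (is_12m) cfg$study_end - 60 else anchor + 280
        dates <- dates[dates <= horizon]
        days <- vapply(seq_along(dates), function(j)
          if (use_triptan) rint(3, 9) else rint(5, 14), numeric(1))
        rx_rows <- tibble(patient_id = pid, rx_date = dates,
                          molecule = mol,
                          days_supplied = as.integer(days))
        if (runif(1) < 0.35) {  # second acute class, still below threshold
          mol2 <- if (use_triptan) sample_weighted(NSAID_POOL, NSAID_W)
                  else sample_weighted(TRIPTAN_POOL, TRIPTAN_W)
          k2 <- rint(1, 3)
          d2 <- anchor + 15 + c(0, cumsum(vapply(
            seq_len(max(0, k2 - 1)), function(j) rint(32, 60), numeric(1))))
          d2 <- d2[d2 <= horizon]
          rx_rows <- bind_rows(rx_rows, tibble(
            patient_id = pid, rx_date = d2, molecule = mol2,
            days_supplied = as.integer(vapply(seq_along(d2), function(j)
              if (use_triptan) rint(5, 14) else rint(3, 9), numeric(1)))))
        }
        yr <- as.character(max(min(as.integer(format(anchor, "%Y")),
                                   max(prev_years)), min(prev_years)))
        if (runif(1) < cfg$p_preventive_by_year[[yr]]) {
          np <- rint(1, 4)
          # >= 32 days guarantees the preventive starts in a later calendar
          # month than the first acute claim, keeping the before-window mean
          # strictly above the after-window mean for these constructed
          # no-decrease negatives
          p0 <- anchor + rint(32, 150)
          prev_mol <- sample_weighted(CONV_PREV_POOL, CONV_PREV_W)
          if (np >= 3) {
            # eligible continuer: acute use must decrease after the start,
            # so this patient is a constructed negative for the
            # no-decrease phenotype
            mp <- month_floor(p0)
            before_dates <- seq(mp, by = "-1 month", length.out = 4)[4:2] + 9
            before_dates <- before_dates[before_dates >= anchor]
            after_date <- seq(mp, by = "1 month", length.out = 2)[2] + 9
            rx_rows <- tibble(
              patient_id = pid,
              rx_date = c(anchor, before_dates, after_date),
              molecule = mol,
              days_supplied = as.integer(c(
                if (use_triptan) 9 else 14,
                rep(if (use_triptan) 8L else 12L, length(before_dates)),
                2L)))
          }
          rx_rows <- bind_rows(rx_rows, tibble(
            patient_id = pid, rx_date = p0 + 30 * (seq_len(np) - 1),
            molecule = prev_mol, days_supplied = 30L))
        }
      }
      anchor <- min(c(anchor, rx_rows$rx_date))
      m_a <- month_floor(anchor)
    } else if (runif(1) < 0.25) {
      # headache-only distractor: analgesics without any migraine diagnosis
      k <- rint(1, 3)
      dates <- anchor + c(0, cumsum(vapply(seq_len(max(0, k - 1)),
                                           function(j) rint(32, 60),
                                           numeric(1))))
      rx_rows <- tibble(
        patient_id = pid, rx_date = dates,
        molecule = sample_weighted(NSAID_POOL, NSAID_W),
        days_supplied = as.integer(vapply(seq_along(dates), function(j)
          rint(5, 14), numeric(1))))
    }

    # diagnosis claims: one at the anchor, then monthly-cadence revisits
    dx_code <- if (migraine) "G43" else "R51"
    last_claim <- max(c(anchor, if (!is.null(rx_rows)) rx_rows$rx_date))
    horizon <- if (is_12m) {
      anchor + 370 + rint(5, min(55, max(5,
        as.integer(cfg$study_end - anchor) - 375)))
    } else {
      min(anchor + rint(30, 300), cfg$study_end)
    }
    horizon <- max(horizon, last_claim)
    revisit <- anchor + cumsum(vapply(seq_len(16), function(j)
      rint(25, 45), numeric(1)))
    revisit <- revisit[revisit <= horizon - 5]
    dx_dates <- c(anchor, revisit, if (is_12m) horizon)
    dx_rows <- tibble(patient_id = pid, service_date = dx_dates,
                      icd10 = dx_code,
                      suspected = c(FALSE, runif(length(dx_dates) - 1) < 0.1),
                      facility_id = fac_i)
    if (cluster) {
      dx_rows <- bind_rows(dx_rows, tibble(
        patient_id = pid, service_date = anchor + rint(0, 60),
        icd10 = "G44.0", suspected = FALSE, facility_id = fac_i))
    } else if (migraine && runif(1) < 0.01) {
      # suspected-only cluster headache: stays in the cohort
      dx_rows <- bind_rows(dx_rows, tibble(
        patient_id = pid, service_date = anchor + rint(0, 60),
        icd10 = "G44.0", suspected = TRUE, facility_id = fac_i))
    }

    # enrollment; planted short-baseline violators start late
    enr_start <- if (short_baseline) anchor - rint(30, 120)
                 else anchor - 183 - rint(31, 365)
    age <- if (underage) rint(16, 17)
           else max(19, min(74, round(rnorm(1, cfg$age_mean_sd[1],
                                            cfg$age_mean_sd[2]))))
    birth_year <- as.integer(format(anchor, "%Y")) - age

    # imaging around the first diagnosis
    p_img <- if (is_cp) cfg$p_imaging_given_CP else cfg$p_imaging_given_HP
    if (runif(1) < p_img) {
      img_date <- max(anchor + rint(-90, 90), enr_start)
      pr_rows <- tibble(patient_id = pid, service_date = img_date,
                        modality = if (runif(1) < 0.5) "CT" else "MRI",
                        facility_id = fac_i)
    }

    last_claim <- max(c(dx_rows$service_date,
                        if (!is.null(rx_rows)) rx_rows$rx_date,
                        if (!is.null(pr_rows)) pr_rows$service_date))

    # background comorbidity and unrelated diagnosis noise
    if (runif(1) < cfg$p_comorbidity_noise) {
      kn <- rint(1, 3)
      nd <- vapply(seq_len(kn), function(j)
        as.numeric(rdate(enr_start, last_claim)), numeric(1))
      dx_rows <- bind_rows(dx_rows, tibble(
        patient_id = pid,
        service_date = as.Date(nd, origin = "1970-01-01"),
        icd10 = vapply(seq_len(kn), function(j)
          NOISE_COMORBID[rint(1, length(NOISE_COMORBID))], character(1)),
        suspected = runif(kn) < 0.2, facility_id = fac_i))
    }
    if (runif(1) < cfg$p_other_noise) {
      nd <- rdate(enr_start, last_claim)
      dx_rows <- bind_rows(dx_rows, tibble(
        patient_id = pid, service_date = nd,
        icd10 = NOISE_OTHER[rint(1, length(NOISE_OTHER))],
        suspected = runif(1) < 0.2, facility_id = fac_i))
    }

    enr_l[[pid]] <- tibble(
      patient_id = pid, birth_year = birth_year, sex = sex,
      start_date = enr_start,
      end_date = if (runif(1) < 0.8) as.Date(NA) else
        last_claim + rint(10, 90))
    dx_l[[pid]] <- dx_rows
    rx_l[[pid]] <- rx_rows
    pr_l[[pid]] <- pr_rows

    in_headache <- !violator
    in_migraine <- migraine && in_headache && !cluster
    truth_l[[pid]] <- tibble(
      patient_id = pid, archetype = archetype,
      in_headache_cohort = in_headache,
      in_migraine_cohort = in_migraine,
      in_12m_population = in_migraine && is_12m,
      is_triptan_switcher = phenotype == "switch",
      is_moh_pattern = phenotype == "moh",
      is_case3_pattern = phenotype == "case3",
      case3_group = case3_group,
      has_cluster_headache = cluster,
      headache_index = if (in_headache) m_a else as.Date(NA),
      migraine_index = if (in_migraine) anchor else as.Date(NA))
  }

  finalize <- function(lst, empty, ...) {
    d <- bind_rows(lst)
    if (nrow(d) == 0) return(empty)
    arrange(d, ...)
  }
  bundle <- list(
    enrollment = finalize(enr_l, bundle_tables$enrollment, .data$patient_id),
    diagnoses = finalize(dx_l, bundle_tables$diagnoses, .data$patient_id,
                         .data$service_date, .data$icd10),
    prescriptions = finalize(rx_l, bundle_tables$prescriptions,
                             .data$patient_id, .data$rx_date,
                             .data$molecule),
    procedures = finalize(pr_l, bundle_tables$procedures, .data$patient_id,
                          .data$service_date),
    facilities = bundle_tables$facilities,
    codelist = default_codelist())
  class(bundle) <- "claims_bundle"
  validate_claims_bundle(bundle)
  list(bundle = bundle, truth = bind_rows(truth_l))
}

#' Write a simulated bundle and its ground truth
#'
#' Writes the six bundle CSVs via [write_claims_bundle()] plus
#' `truth.csv` with the planted labels.
#'
#' @param sim Output of [simulate_bundle()].
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_claims_bundle(sim$bundle, dir)
  truth <- sim$truth
  truth$headache_index <- format_iso_date(truth$headache_index)
  truth$migraine_index <- format_iso_date(truth$migraine_index)
  tp <- file.path(dir, "truth.csv")
  write.csv(truth, tp, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(paths, truth = tp))
}
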