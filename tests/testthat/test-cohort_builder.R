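test_that("the headache index is the first day of the month of the first claim", {
  b <- toy_bundle(
    enrollment = enr_row("P1", birth_year = 1989),
    diagnoses = dx_row("P1", "2019-03-17", "R51"))
  hc <- build_headache_cohort(b)
  expect_equal(nrow(hc), 1)
  expect_equal(hc$index_date, as.Date("2019-03-01"))
  expect_equal(hc$first_dx_date, as.Date("2019-03-17"))
  expect_equal(hc$index_diagnosis, "headache")
})

test_that("age and baseline-enrollment criteria exclude at the boundary", {
  # 17 at index (born mid-1992, index early 2010): excluded
  b <- toy_bundle(
    enrollment = dplyr::bind_rows(
      enr_row("P_young", birth_year = 2001, start = "2018-01-01"),
      enr_row("P_adult", birth_year = 2000, start = "2018-01-01"),
      enr_row("P_short", birth_year = 1980, start = "2019-01-01")),
    diagnoses = dplyr::bind_rows(
      dx_row("P_young", "2019-03-10"),
      dx_row("P_adult", "2019-03-10"),
      dx_row("P_short", "2019-03-10")))
  hc <- build_headache_cohort(b)
  # born 2001, index 2019-03-01, before June 30 birthday: age 17 -> excluded
  expect_false("P_young" %in% hc$patient_id)
  expect_true("P_adult" %in% hc$patient_id)  # age 18
  # enrolled 2019-01-01, index 2019-03-01: 59 days of baseline -> excluded
  expect_false("P_short" %in% hc$patient_id)
  at <- attr(hc, "attrition")
  expect_equal(sum(at$n), 3)
  expect_equal(at$n[at$reason == "included"], 1)
})

test_that("suspected diagnoses count toward the headache cohort", {
  b <- toy_bundle(
    enrollment = enr_row("P1"),
    diagnoses = dx_row("P1", "2019-03-17", "G43", suspected = TRUE))
  hc <- build_headache_cohort(b)
  expect_equal(nrow(hc), 1)
  expect_equal(hc$index_diagnosis, "migraine")
})

test_that("the three-patient fixture builds a cohort of exactly two", {
  hc <- build_headache_cohort(fixture_bundle())
  expect_setequal(hc$patient_id, c("P1", "P2"))
  mc <- build_migraine_cohort(fixture_bundle(), hc)
  expect_equal(mc$patient_id, "P2")
  expect_equal(mc$index_date, as.Date("2020-05-10"))  # first triptan claim
})

test_that("the migraine cohort needs a migraine drug and no confirmed cluster headache", {
  base_enr <- dplyr::bind_rows(enr_row("A"), enr_row("B"), enr_row("C"))
  base_dx <- dplyr::bind_rows(
    dx_row("A", "2019-05-03", "G43"),
    dx_row("B", "2019-05-03", "G43"),
    dx_row("C", "2019-05-03", "G43"),
    dx_row("B", "2019-07-01", "G44.0", suspected = TRUE),
    dx_row("C", "2019-07-01", "G44.0", suspected = FALSE))
  cl <- dplyr::bind_rows(default_codelist(),
                         tibble::tibble(molecule = "vitaminC",
                                        drug_class = "other",
                                        treatment_type = "neither"))
  b <- toy_bundle(
    enrollment = base_enr, diagnoses = base_dx,
    prescriptions = dplyr::bind_rows(
      rx_row("A", "2019-05-10", "vitaminC", 30),     # no migraine drug
      rx_row("B", "2019-05-10", "sumatriptan", 10),  # suspected-only G44.0
      rx_row("C", "2019-05-10", "sumatriptan", 10)), # confirmed G44.0
    codelist = cl)
  hc <- build_headache_cohort(b)
  mc <- build_migraine_cohort(b, hc, codelist = cl)
  expect_equal(mc$patient_id, "B")
  at <- attr(mc, "attrition")
  expect_equal(at$n[at$reason == "no_migraine_treatment"], 1)
  expect_equal(at$n[at$reason == "confirmed_cluster_headache"], 1)
})

test_that("the 12-month population boundary is inclusive at 365 days", {
  cohort <- tibble::tibble(patient_id = c("A", "B", "C", "D", "E"),
                           follow_up_days = c(365L, 364L, 400L, 0L, 366L))
  expect_setequal(select_12m_population(cohort)$patient_id,
                  c("A", "C", "E"))
})

test_that("facility bands split at the statutory bed counts", {
  expect_equal(classify_facility_band(c(0, 19, 20, 99, 100, 199, 200, 299,
                                        300, 499, 500, 1200)),
               c("CP_0_19", "CP_0_19", "HP_20_99", "HP_20_99", "HP_100_199",
                 "HP_100_199", "HP_200_299", "HP_200_299", "HP_300_499",
                 "HP_300_499", "HP_500_plus", "HP_500_plus"))
  expect_error(classify_facility_band(-1), "non-negative")
})

test_that("imaging is attributed within an inclusive 90-day window of the first claim", {
  mk <- function(offset, facility = "FHP") {
    toy_bundle(
      enrollment = enr_row("P1"),
      diagnoses = dx_row("P1", "2019-06-01", "R51", facility = facility),
      procedures = pr_row("P1", d("2019-06-01") + offset, "CT",
                          facility = facility))
  }
  hc90 <- build_headache_cohort(mk(90))
  expect_true(hc90$imaging_done)
  expect_equal(hc90$imaging_site, "HP")  # 520-bed facility
  hc91 <- build_headache_cohort(mk(91))
  expect_false(hc91$imaging_done)
  expect_equal(hc91$imaging_site, "none")
  hcm90 <- build_headache_cohort(mk(-90, facility = "FCP"))
  expect_true(hcm90$imaging_done)
  expect_equal(hcm90$imaging_site, "CP")
})

test_that("baseline comorbidity flags follow the prefix map and baseline window", {
  b <- toy_bundle(
    enrollment = enr_row("P1"),
    diagnoses = dplyr::bind_rows(
      dx_row("P1", "2019-06-01", "R51"),
      dx_row("P1", "2019-05-01", "I10"),                    # in baseline
      dx_row("P1", "2019-04-01", "C71"),                    # brain malignancy
      dx_row("P1", "2019-03-01", "F32", suspected = TRUE),  # suspected: no
      dx_row("P1", "2018-01-10", "E11")))                   # before window
  hc <- build_headache_cohort(b)
  expect_true(hc$cm_hypertension)
  expect_true(hc$cm_any_cardiovascular)
  expect_true(hc$cm_brain_malignancy)
  expect_false(hc$cm_other_malignancy)  # C71 excluded by definition
  expect_false(hc$cm_mood_disorders)    # suspected claims do not count
  expect_false(hc$cm_diabetes_mellitus) # outside the 183-day window
  expect_true(hc$cm_any)
})

test_that("cohorts nest and attrition is conserved on simulated data", {
  res <- shared_pipeline()
  expect_true(all(res$migraine_cohort$patient_id %in%
                    res$headache_cohort$patient_id))
  expect_true(all(res$population_12m$patient_id %in%
                    res$migraine_cohort$patient_id))
  at <- res$attrition
  hc_at <- at[at$cohort == "headache", ]
  expect_equal(hc_at$n[hc_at$reason == "included"],
               nrow(res$headache_cohort))
  # simulated truth is recovered exactly
  tr <- shared_sim()$truth
  expect_setequal(res$headache_cohort$patient_id,
                  tr$patient_id[tr$in_headache_cohort])
  expect_setequal(res$migraine_cohort$patient_id,
                  tr$patient_id[tr$in_migraine_cohort])
  expect_setequal(res$population_12m$patient_id,
                  tr$patient_id[tr$in_12m_population])
})
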