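base_date <- as.Date("2020-01-01")

mol_episode <- function(pid, start_day, end_day, molecule,
                        class = "triptan") {
  tibble::tibble(
    patient_id = pid, level = "molecule", key = molecule,
    drug_class = class, start_date = base_date + start_day,
    supply_end_date = base_date + end_day,
    period_days = as.integer(end_day - start_day), n_claims = 1L,
    total_days_supplied = as.integer(end_day - start_day))
}

expo_months <- function(pid, triptan, nsaid = rep(0, length(triptan)),
                        from = "2020-01-01") {
  months <- seq(as.Date(from), by = "1 month", length.out = length(triptan))
  tibble::tibble(
    patient_id = pid, month = months,
    acetaminophen_nsaid = nsaid, triptan = triptan,
    ergotamine = 0, triptan_ergotamine = triptan,
    total_acute = pmin(nsaid + triptan, 31))
}

test_that("a second triptan starting within 60 days of the first's supply end is a switch", {
  ep <- dplyr::bind_rows(
    mol_episode("P1", 0, 30, "sumatriptan"),
    mol_episode("P1", 60, 90, "rizatriptan"))  # 30 days after supply end
  c1 <- detect_triptan_switch(ep)
  expect_true(c1$case1)
  expect_equal(c1$from_molecule, "sumatriptan")
  expect_equal(c1$to_molecule, "rizatriptan")
  expect_equal(c1$switch_date, base_date + 60)
})

test_that("one molecule throughout, simultaneous starts, and distant restarts are not switches", {
  one <- dplyr::bind_rows(mol_episode("P1", 0, 30, "sumatriptan"),
                          mol_episode("P1", 120, 150, "sumatriptan"))
  expect_false(detect_triptan_switch(one)$case1)
  same_day <- dplyr::bind_rows(mol_episode("P2", 0, 30, "sumatriptan"),
                               mol_episode("P2", 0, 30, "rizatriptan"))
  expect_false(detect_triptan_switch(same_day)$case1)
  # overlap counts as addition by default but as switch when configured
  overlap <- dplyr::bind_rows(mol_episode("P3", 0, 60, "sumatriptan"),
                              mol_episode("P3", 30, 90, "rizatriptan"))
  expect_false(detect_triptan_switch(overlap)$case1)
  expect_true(detect_triptan_switch(
    overlap, count_overlap_as_switch = TRUE)$case1)
  # beyond the window: a fresh start, not a switch
  far <- dplyr::bind_rows(mol_episode("P4", 0, 30, "sumatriptan"),
                          mol_episode("P4", 120, 150, "rizatriptan"))
  expect_false(detect_triptan_switch(far)$case1)
})

test_that("three consecutive months at the triptan threshold flag MOH risk", {
  c2 <- detect_moh_risk(expo_months("P1", c(10, 10, 10)))
  expect_true(c2$case2)
  expect_equal(c2$first_overuse_month, as.Date("2020-01-01"))
  expect_equal(c2$n_consecutive_overuse_months, 3L)
  expect_false(detect_moh_risk(expo_months("P1", rep(9, 12)))$case2)
})

test_that("a broken run restarts the consecutive-month count", {
  c2 <- detect_moh_risk(expo_months("P1", c(10, 10, 0, 10, 10, 10)))
  expect_true(c2$case2)
  expect_equal(c2$first_overuse_month, as.Date("2020-04-01"))
  expect_false(detect_moh_risk(expo_months("P1", c(10, 10, 0, 10, 10)))$case2)
})

test_that("calendar gaps in the exposure series break runs", {
  ex <- dplyr::bind_rows(expo_months("P1", c(10, 10)),
                         expo_months("P1", 10, from = "2020-06-01"))
  expect_false(detect_moh_risk(ex)$case2)
})

test_that("the analgesic threshold is separate from the triptan threshold", {
  expect_true(detect_moh_risk(
    expo_months("P1", rep(0, 3), nsaid = c(15, 15, 15)))$case2)
  expect_false(detect_moh_risk(
    expo_months("P1", rep(0, 3), nsaid = c(14, 14, 14)))$case2)
})

test_that("MOH detection matches exhaustive window enumeration on random series", {
  set.seed(46)
  thr <- moh_thresholds()
  for (i in 1:400) {
    n <- sample.int(24, 1)
    present <- sort(sample.int(24, n))
    tript <- sample(0:14, n, replace = TRUE)
    nsaid <- sample(0:18, n, replace = TRUE)
    ex <- tibble::tibble(
      patient_id = "PX",
      month = seq(as.Date("2020-01-01"), by = "1 month",
                  length.out = 24)[present],
      acetaminophen_nsaid = nsaid, triptan = tript, ergotamine = 0,
      triptan_ergotamine = tript,
      total_acute = pmin(nsaid + tript, 28))
    got <- detect_moh_risk(ex, thr)
    mi <- as.integer(format(ex$month, "%Y")) * 12L +
      as.integer(format(ex$month, "%m")) - 1L
    want <- oracle_moh(mi, tript, nsaid, thr)
    expect_equal(got$case2, want$case2, info = paste("case", i))
    if (want$case2) {
      got_mi <- as.integer(format(got$first_overuse_month, "%Y")) * 12L +
        as.integer(format(got$first_overuse_month, "%m")) - 1L
      expect_equal(got_mi, want$first_month_idx)
      expect_equal(got$n_consecutive_overuse_months, want$run_len)
    }
  }
})

test_that("raising any MOH threshold never grows the flagged set", {
  set.seed(47)
  exs <- lapply(1:60, function(i) {
    n <- sample.int(18, 1)
    tript <- sample(0:16, n, replace = TRUE)
    nsaid <- sample(0:20, n, replace = TRUE)
    expo_months(paste0("P", i), tript, nsaid)
  })
  ex <- dplyr::bind_rows(exs)
  flagged <- function(thr) {
    r <- detect_moh_risk(ex, thr)
    r$patient_id[r$case2]
  }
  base <- flagged(moh_thresholds())
  expect_true(all(flagged(moh_thresholds(
    triptan_ergot_days_per_month = 12)) %in% base))
  expect_true(all(flagged(moh_thresholds(
    analgesic_days_per_month = 18)) %in% base))
  expect_true(all(flagged(moh_thresholds(run_months = 4)) %in% base))
})

test_that("no decrease after preventive start includes equality and needs 3 months' continuation", {
  cls_ep <- function(end_day) tibble::tibble(
    patient_id = "P1", level = "class", key = "antiepileptic",
    drug_class = "antiepileptic", start_date = as.Date("2020-04-15"),
    supply_end_date = as.Date("2020-04-15") + end_day,
    period_days = as.integer(end_day), n_claims = 3L,
    total_days_supplied = as.integer(end_day))
  ex_equal <- expo_months("P1", rep(6, 7))  # Jan..Jul, 6 days every month
  r <- detect_case3(cls_ep(120), ex_equal, "conventional")
  expect_true(r$eligible)
  expect_true(r$case3)  # 6.0 before vs 6.0 after
  expect_equal(r$mean_acute_days_before, 6)
  expect_equal(r$mean_acute_days_after, 6)

  ex_drop <- expo_months("P1", c(10, 10, 10, 4, 4, 4, 0))
  r2 <- detect_case3(cls_ep(120), ex_drop, "conventional")
  expect_true(r2$eligible)
  expect_false(r2$case3)

  # 60-day episode: ineligible regardless of acute use
  r3 <- detect_case3(cls_ep(60), ex_equal, "conventional")
  expect_false(r3$eligible)
  expect_false(r3$case3)

  # anti-CGRP mAb episodes are invisible to the conventional group
  mab <- cls_ep(120)
  mab$key <- mab$drug_class <- "anti_cgrp_mab"
  expect_equal(nrow(detect_case3(cls_ep(120), ex_equal, "anti_cgrp_mab")), 0)
  expect_true(detect_case3(mab, ex_equal, "anti_cgrp_mab")$case3)
})

test_that("case flags and summary use the right denominators", {
  res <- shared_pipeline()
  fl <- res$case_flags
  expect_true(all(fl$case3_1 <= fl$case3_eligible_conventional))
  expect_true(all(fl$case3_2 <= fl$case3_eligible_mab))
  expect_true(all(fl$moh_run_months[fl$case2] >= 3))
  t4 <- res$table4
  expect_equal(t4$denominator[t4$group == "case1"],
               nrow(res$population_12m))
  expect_equal(t4$denominator[t4$group == "case3_1"],
               sum(fl$case3_eligible_conventional))
  expect_equal(t4$n[t4$group == "case2"], sum(fl$case2))
  expect_equal(t4$pct[t4$group == "case2"],
               pct(sum(fl$case2), nrow(res$population_12m)))
})

test_that("all three detectors recover the planted phenotypes exactly", {
  res <- shared_pipeline()
  tr <- shared_sim()$truth
  fl <- res$case_flags
  expect_setequal(fl$patient_id[fl$case1],
                  tr$patient_id[tr$is_triptan_switcher])
  expect_setequal(fl$patient_id[fl$case2],
                  tr$patient_id[tr$is_moh_pattern])
  expect_setequal(fl$patient_id[fl$case3_1 | fl$case3_2],
                  tr$patient_id[tr$is_case3_pattern])
  # groups line up with the planted preventive class
  planted_mab <- tr$patient_id[tr$is_case3_pattern &
                                 tr$case3_group == "anti_cgrp_mab"]
  expect_setequal(fl$patient_id[fl$case3_2], planted_mab)
})
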