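base_date <- as.Date("2020-01-01")

mk_episode <- function(pid, start_day, end_day, class) {
  tibble::tibble(
    patient_id = pid, level = "class", key = class, drug_class = class,
    start_date = base_date + start_day, supply_end_date = base_date + end_day,
    period_days = as.integer(end_day - start_day), n_claims = 1L,
    total_days_supplied = as.integer(end_day - start_day))
}

test_that("a single-class patient has one line with the 'only' cell", {
  lines <- assign_lines(mk_episode("P1", 0, 30, "acetaminophen_nsaid"))
  expect_equal(nrow(lines), 1)
  expect_equal(lines$classes, "acetaminophen_nsaid")
  expect_true(lines$has_acute)
  expect_false(lines$has_preventive)
  expect_equal(classify_regimen("acetaminophen_nsaid"),
               "acetaminophen_nsaid_only")
})

test_that("a class starting within the grace window joins the first line", {
  ep <- dplyr::bind_rows(mk_episode("P1", 0, 30, "acetaminophen_nsaid"),
                         mk_episode("P1", 10, 40, "triptan"))
  lines <- assign_lines(ep, grace_days = 30)
  expect_equal(nrow(lines), 1)
  expect_equal(lines$classes, "acetaminophen_nsaid+triptan")
  cells <- classify_regimen(c("acetaminophen_nsaid", "triptan"))
  expect_setequal(cells, c("acetaminophen_nsaid_plus_triptan",
                           "triptan_plus_acetaminophen_nsaid"))
})

test_that("a late new class after supply lapse starts the next line", {
  ep <- dplyr::bind_rows(mk_episode("P1", 0, 60, "triptan"),
                         mk_episode("P1", 100, 160, "antiepileptic"))
  lines <- assign_lines(ep)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$classes, c("triptan", "antiepileptic"))
  expect_equal(lines$end_date[1], base_date + 99)  # day before line 2
  expect_equal(lines$start_date[2], base_date + 100)
})

test_that("a same-class restart after all supply has lapsed advances the line", {
  ep <- dplyr::bind_rows(mk_episode("P1", 0, 30, "triptan"),
                         mk_episode("P1", 200, 230, "triptan"))
  lines <- assign_lines(ep)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$classes, c("triptan", "triptan"))
})

test_that("a new class while supply is ongoing but after grace advances the line", {
  ep <- dplyr::bind_rows(mk_episode("P1", 0, 120, "triptan"),
                         mk_episode("P1", 50, 140, "ca_channel_blocker"))
  lines <- assign_lines(ep, grace_days = 30)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$classes[2], "ca_channel_blocker")
})

test_that("at most max_lines ordinals are emitted", {
  ep <- dplyr::bind_rows(lapply(0:5, function(k)
    mk_episode("P1", 200 * k, 200 * k + 30, "triptan")))
  lines <- assign_lines(ep, max_lines = 4)
  expect_equal(lines$ordinal, 1:4)
})

test_that("three-class regimens fall into the preventive pairing cells", {
  cells <- classify_regimen(c("triptan", "antiepileptic",
                              "ca_channel_blocker"))
  expect_setequal(cells, c(
    "triptan_plus_preventive",
    "antiepileptic_plus_other_preventive",
    "ca_channel_blocker_plus_other_preventive"))
  # two acute companions with no preventive: residual cell
  cells2 <- classify_regimen(c("triptan", "acetaminophen_nsaid",
                               "ergotamine"))
  expect_true(all(grepl("_plus_others$", cells2)))
})

test_that("the summary table is self-consistent with mirrored pair cells", {
  res <- shared_pipeline()
  t3 <- res$table3
  for (k in unique(t3$ordinal)) {
    den <- t3$n[t3$ordinal == k & t3$label == "n_patients"]
    expect_true(all(t3$n[t3$ordinal == k] <= den))
    # every percentage is pct(n, denominator)
    sub <- t3[t3$ordinal == k, ]
    expect_equal(sub$pct, pct(sub$n, den))
    # mirrored pair cells are equal
    pair <- function(a, b) {
      na <- sub$n[sub$label == paste0(a, "_plus_", b)]
      nb <- sub$n[sub$label == paste0(b, "_plus_", a)]
      expect_equal(length(na), length(nb))
      if (length(na) == 1) expect_equal(na, nb)
    }
    pair("acetaminophen_nsaid", "triptan")
    pair("acetaminophen_nsaid", "ergotamine")
    pair("triptan", "ergotamine")
  }
  # patient counts are non-increasing over ordinals
  denoms <- vapply(sort(unique(t3$ordinal)), function(k)
    t3$n[t3$ordinal == k & t3$label == "n_patients"], integer(1))
  expect_true(all(diff(denoms) <= 0))
})

test_that("per-class cell counts sum to the class total", {
  res <- shared_pipeline()
  t3 <- res$table3
  for (k in unique(t3$ordinal)) {
    sub <- t3[t3$ordinal == k, ]
    for (cl in c("triptan", "acetaminophen_nsaid", "antiepileptic",
                 "ca_channel_blocker")) {
      total <- sub$n[sub$label == cl]
      cells <- sub$n[grepl(paste0("^", cl, "_(only|plus)"), sub$label)]
      if (length(total) == 1 && total > 0) {
        expect_equal(sum(cells), total,
                     info = paste("ordinal", k, "class", cl))
      }
    }
  }
})
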