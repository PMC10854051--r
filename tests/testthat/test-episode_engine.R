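base_date <- as.Date("2020-01-01")

claims_at <- function(days, supply, molecule = "sumatriptan") {
  tibble::tibble(patient_id = "PX", rx_date = base_date + days,
                 molecule = molecule, days_supplied = as.integer(supply))
}

test_that("refills within the 60-day gap chain into one episode", {
  ep <- chain_episodes(claims_at(c(0, 35), c(30, 30)), level = "molecule")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_date, base_date)
  expect_equal(ep$supply_end_date, base_date + 65)
  expect_equal(ep$period_days, 65L)
  expect_equal(ep$n_claims, 2L)
})

test_that("a refill beyond the gap opens a new episode", {
  # supply of the first claim ends day 10; gap to day 75 is 65 > 60
  ep <- chain_episodes(claims_at(c(0, 75), c(10, 10)), level = "molecule")
  expect_equal(nrow(ep), 2)
  expect_equal(ep$start_date, base_date + c(0, 75))
  # exactly at the limit: gap of 60 chains
  ep2 <- chain_episodes(claims_at(c(0, 70), c(10, 10)), level = "molecule")
  expect_equal(nrow(ep2), 1)
})

test_that("a single claim is its own episode with period equal to its supply", {
  ep <- chain_episodes(claims_at(0, 14), level = "molecule")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$period_days, 14L)
  expect_equal(ep$total_days_supplied, 14L)
})

test_that("molecule-level and class-level chaining differ for two molecules of one class", {
  rx <- dplyr::bind_rows(claims_at(0, 10, "sumatriptan"),
                         claims_at(30, 10, "rizatriptan"))
  expect_equal(nrow(chain_episodes(rx, level = "molecule")), 2)
  expect_equal(nrow(chain_episodes(rx, level = "class")), 1)
})

test_that("chaining matches the day-grid oracle on random claim sets", {
  set.seed(42)
  for (i in 1:400) {
    n <- sample.int(10, 1)
    gap <- sample(c(15, 30, 60, 90), 1)
    rx <- random_claims(n)
    ep <- chain_episodes(rx, level = "molecule", gap_days = gap)
    orc <- oracle_chain(as.numeric(rx$rx_date), rx$days_supplied, gap)
    expect_equal(nrow(ep), nrow(orc), info = paste("case", i))
    expect_equal(as.numeric(ep$start_date), orc$start)
    expect_equal(as.numeric(ep$supply_end_date), orc$end)
    expect_equal(ep$n_claims, orc$n_claims)
    expect_equal(ep$total_days_supplied, orc$total_days)
  }
})

test_that("chaining is idempotent and conserves supplied days", {
  set.seed(43)
  for (i in 1:30) {
    rx <- random_claims(sample.int(10, 1))
    ep <- chain_episodes(rx, level = "molecule")
    expect_equal(sum(ep$total_days_supplied), sum(rx$days_supplied))
    # feed the episodes back as single claims covering their own period
    again <- chain_episodes(
      tibble::tibble(patient_id = ep$patient_id, rx_date = ep$start_date,
                     molecule = ep$key, days_supplied = ep$period_days),
      level = "molecule")
    expect_equal(again$start_date, ep$start_date)
    expect_equal(again$supply_end_date, ep$supply_end_date)
  }
})

test_that("increasing the gap never increases the episode count", {
  set.seed(44)
  for (i in 1:30) {
    rx <- random_claims(sample.int(10, 1))
    counts <- vapply(c(0, 15, 30, 60, 90, 120), function(g)
      nrow(chain_episodes(rx, level = "molecule", gap_days = g)),
      integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("stockpiling adds overlapping supply instead of truncating it", {
  rx <- claims_at(c(0, 10), c(30, 30))
  expect_equal(chain_episodes(rx, level = "molecule")$supply_end_date,
               base_date + 40)
  expect_equal(chain_episodes(rx, level = "molecule",
                              stockpile = TRUE)$supply_end_date,
               base_date + 60)
})

test_that("monthly exposure attributes full supply to the prescription month", {
  rx <- tibble::tibble(patient_id = "PX",
                       rx_date = as.Date("2021-04-20"),
                       molecule = "rizatriptan", days_supplied = 10L)
  ex <- monthly_acute_days(rx)
  expect_equal(ex$month, as.Date("2021-04-01"))
  expect_equal(ex$triptan, 10)
  expect_equal(ex$triptan_ergotamine, 10)
  expect_equal(ex$total_acute, 10)
})

test_that("monthly sums are capped at the month's length", {
  rx <- dplyr::bind_rows(
    rx_row("PX", "2021-04-02", "loxoprofen", 20),
    rx_row("PX", "2021-04-25", "loxoprofen", 20))
  ex <- monthly_acute_days(rx)
  expect_equal(ex$acetaminophen_nsaid, 30)  # April has 30 days
})

test_that("exposure never leaks across months and conserves uncapped days", {
  set.seed(45)
  for (i in 1:20) {
    n <- sample.int(8, 1)
    rx <- tibble::tibble(
      patient_id = "PX",
      rx_date = as.Date("2021-01-01") + sample.int(360, n, replace = TRUE),
      molecule = "rizatriptan",
      days_supplied = sample.int(9, n, replace = TRUE))
    ex <- monthly_acute_days(rx)
    expect_setequal(format(ex$month, "%Y-%m"), format(rx$rx_date, "%Y-%m"))
    by_month <- tapply(rx$days_supplied, format(rx$rx_date, "%Y-%m"), sum)
    for (m in names(by_month)) {
      first <- as.Date(paste0(m, "-01"))
      cap <- as.integer(seq(first, by = "1 month", length.out = 2)[2] - first)
      got <- ex$triptan[format(ex$month, "%Y-%m") == m]
      expect_equal(got, min(by_month[[m]], cap))
    }
  }
})

test_that("prescription-period quantiles use linear interpolation", {
  ep <- tibble::tibble(
    patient_id = paste0("P", 1:4), level = "class",
    key = "antiepileptic", drug_class = "antiepileptic",
    start_date = base_date, supply_end_date = base_date + c(10, 20, 30, 100),
    period_days = c(10L, 20L, 30L, 100L), n_claims = 1L,
    total_days_supplied = c(10L, 20L, 30L, 100L))
  s <- summarize_prescription_periods(ep)
  expect_equal(s$median, 25)
  s3 <- summarize_prescription_periods(ep[1:3, ])
  expect_equal(s3$median, 20)
  expect_equal(nrow(summarize_prescription_periods(ep[0, ])), 0)
})
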