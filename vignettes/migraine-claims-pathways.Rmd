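---
title: "Methods: migraine treatment pathways from administrative claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: migraine treatment pathways from administrative claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Administrative claims record diagnoses, prescriptions and procedures
generated for reimbursement, not for research. They carry no treatment
intent, no symptom frequency and no over-the-counter drug use, yet they are
often the only population-scale view of how migraine is actually managed.
This package turns a claims extract (five CSV tables: enrollment spans,
ICD-10 diagnosis claims with a suspected flag, prescriptions with days
supplied, CT/MRI procedure claims and a facility bed-count registry) into
the standard outputs of a migraine treatment-pattern study: two nested
cohorts, continuous-prescription episodes, ordinal treatment lines, and
three rule-based phenotypes of patients potentially not managed well by
current therapy.

```{r, eval = FALSE}
library(migrainepaths)
sim <- simulate_bundle(sim_config(n_patients = 1000, seed = 42))
res <- run_pipeline(sim$bundle)
```

## Cohorts and index dates

The **headache cohort** holds adults (≥ 18 years at index) with at least
one R51 (headache) or G43 (migraine) claim — suspected diagnoses count,
since in Japanese claims a "suspected" flag often accompanies the very
visit at which the condition is being worked up — and at least 183 days of
continuous enrollment before the index date. The index date is the first
day of the calendar month of the earliest qualifying claim; month-flooring
reflects how claims tables are often delivered (month-level billing
periods). The **migraine cohort** nests inside it: a G43 claim plus at
least one prescription of a migraine treatment, indexed at that first
prescription, with confirmed (non-suspected) cluster headache (G44.0)
excluded. Follow-up runs from index to the last visit observed anywhere in
the claims. Members with at least 365 days of follow-up form the 12-month
population on which the phenotypes are reported.

Choices that were genuinely open, fixed here and exposed as parameters:

* *"6 months of baseline"* = 183 days; *"12 months of follow-up"* = 365
  days (inclusive boundary). Day counts, not calendar months, keep the
  criteria deterministic.
* Age is derived from birth year alone with a mid-year (June 30) birthday
  convention, because claims carry only a birth year.
* The index prescription of the migraine cohort may precede the first G43
  claim; no temporal order is imposed by default (`strict_order = TRUE`
  restricts to prescriptions from the first G43 month onward).
* Imaging is attributed within an inclusive ± 90-day window of the first
  diagnosis **claim date**, not the month-floored index: the clinical
  anchor is the visit, the month-flooring is an indexing convention.
* The index facility is the facility of the first qualifying claim (ties
  broken deterministically by date, code, facility id); patients imaged at
  both a clinic and a hospital are reported as site `"both"` rather than
  silently assigned to one row.

Baseline comorbidities are flagged from confirmed claims in the 183 days
strictly before index, using standard ICD-10 blocks for the twelve
reported groups (e.g. hypertension I10–I15, mood disorders F30–F39, brain
malignancy C71 carved out of the other-malignancy block C00–C97). The
source study names the groups without listing codes, so the map is a
reconstruction and fully overridable.

## Prescription episodes (drug eras)

A refill belongs to the same episode when its date is at most `gap_days`
(default 60) after the supply-exhaustion date of the prior prescriptions;
the exhaustion date extends by `max(current end, claim date + days
supplied)`, i.e. overlapping refills do not stockpile unused days (a
`stockpile = TRUE` flag switches to additive carry-over). The episode's
*prescription period* is supply end minus start. Whether the 60-day rule
applies to "the same medication" at molecule or at class granularity is
ambiguous in the source description; both levels are implemented
(`level = "molecule"` for period reporting and switch detection,
`level = "class"` for lines and the no-decrease phenotype).

The chaining algorithm is verified against an independent day-grid oracle
that walks the calendar one day at a time with a supply tank — the tests
require exact agreement on episode boundaries, claim counts and day totals
for randomized claim sets.

## Monthly acute exposure

Claims record an as-needed prescription of *n* doses as *n* days of
supply. Following the source study's stated assumption, all supplied days
are attributed to the calendar month of the prescription date (no
spill-over), then capped at the month's length. The combined
triptan + ergotamine sum and the all-acute total are computed from the
uncapped class sums before their own cap, so a month with 6 triptan and 6
analgesic days counts 12 total acute days.

## Treatment lines

Claims never say "second line"; the advancement rule is therefore this
package's own construction, chosen to reproduce the qualitative pattern of
published per-ordinal tables (steep attrition, preventive share rising
with ordinal): line 1 starts at the migraine index, a line's class set is
every drug class whose episode starts within `grace_days` (default 30) of
the line start, and a new line opens at the first episode start that
either introduces a class outside the current set after the grace window
or follows the lapse of all the line's supply. At most four lines are
kept. Each regimen is classified into per-class taxonomy cells (`only`,
one named pairing, `+ preventive` / `+ other preventive`, residual
`+ others`), with the priority rule that any preventive co-prescription
dominates the pairing cells; this keeps each class's cells additive and
the mirrored pair cells (e.g. analgesic + triptan vs triptan + analgesic)
exactly equal.

## The three phenotypes

* **Case 1, triptan switch** — a molecule-level triptan episode starting
  between 0 and `switch_window_days` (default 60) days after the supply
  end of an episode of a *different* triptan. Overlapping distinct
  triptans count as an addition, not a switch (configurable).
* **Case 2, MOH-risk pattern** — at least `run_months` (default 3)
  consecutive calendar months in which triptan + ergotamine days ≥ 10 or
  acetaminophen/NSAID days ≥ 15. The numeric thresholds follow the ICHD-3
  convention for medication overuse; the exact operationalization used by
  the source study sits in an unavailable supplement, so every number is a
  configuration knob, and "more than 3 months" is implemented as ≥ 3
  consecutive months (≥ 4 available by configuration). The detector is
  verified against exhaustive enumeration of all month windows.
* **Case 3, no decrease after preventive start** — among patients whose
  *first* preventive episode of the group (conventional classes for 3-1,
  anti-CGRP mAbs for 3-2) lasted at least `continuation_days` (default
  90), the mean total acute days over the 3 calendar months starting with
  the month of the preventive start is compared with the 3 months strictly
  before; equality counts as "no decrease". Including the start month on
  the "after" side was an open choice, fixed for determinism. The
  published denominators for these two phenotypes are the eligible
  continuers, not the whole 12-month population, and the summary table
  reproduces that.

Raising any MOH threshold can only shrink the flagged set
(anti-monotonicity), which is asserted property-style in the tests.

## The synthetic generator

The generator exists because the data source the analysis is designed for
is proprietary. It is two-layer: archetypes first (no headache / headache
only / migraine, default 20/40/40 at desk scale — deliberately
migraine-enriched relative to a real claims population so that phenotype
counts are testable at a few thousand patients), then claims satisfying
the archetype. Defaults mirror the study's published marginals: window
2018-01-01 to 2022-07-31, 56.6% female, age 40.3 ± 12.9 truncated to
19–74 years, facility mix 77% clinics across the six bed bands, imaging
probability 0.202 at clinics vs 0.727 at hospitals, preventive uptake
rising from 16.1% (2018) to 26.4% (2022), and 69.5% of migraine patients
reaching 12 months of follow-up. Phenotypes are planted among the
12-month migraine patients at the published Case proportions (switch
1.2%, MOH 3.7%, no-decrease 0.6%) as mutually exclusive labels:

* planted MOH patients receive ≥ 10 triptan days (or ≥ 15 analgesic days)
  in each of 3–5 consecutive months; every other patient is built to stay
  strictly below the monthly thresholds (single acute claims of ≤ 9
  triptan / ≤ 14 analgesic days spaced ≥ 32 days apart);
* planted switchers receive a second triptan molecule starting 0–45 days
  after the first molecule's supply end; everyone else uses one triptan
  molecule at most;
* planted no-decrease patients continue a preventive for a 120-day episode
  with equal-or-rising acute days around the start; background preventive
  continuers of ≥ 90 days are built with strictly decreasing acute use so
  they are eligible negatives.

Because positives are built above threshold and negatives strictly below,
detector sensitivity and specificity are 1 *by construction* on planted
data — the tests verify exact patient-for-patient recovery, and the
recovered prevalences are checked against the binomial confidence interval
of the planting probability. Refill gaps for background prescriptions are
uniform on 0–45 days, an arbitrary default documented as such (real-world
refill-gap distributions are unknown).

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: emergent (unplanted) phenotype
mixtures, over-the-counter analgesic use (invisible in claims),
dose/strength information, multi-insurer enrollment churn, correlation of
phenotypes with sex or comorbidity, and realistic molecule market shares
beyond coarse weights. Tests on synthetic data validate the *logic* of the
detectors, not the clinical prevalence of the phenotypes.

## Numerical and reporting conventions

Percentages are rounded half-up to one decimal everywhere
(`pct(n, d) = floor(1000 n / d + 0.5) / 10`); counts are never rounded.
Follow-up months are reported as days / 30.4375. Prescription-period
quantiles use linear interpolation (R type 7). Yearly trends count a
patient in every calendar year with at least one migraine-treatment
prescription (prevalent-year counting), and the year's acute/preventive
shares use that year's contributors as denominator. Problem sizes in the
shipped tests and acceptance script — 4,000 simulated patients, 1,000
random cases per oracle comparison — were chosen as the smallest sizes at
which planted prevalences of a few percent still yield two-digit positive
counts.

## Known limitations

The line-advancement rule and the MOH operationalization are documented
reconstructions of under-specified published definitions; both are
parameterized rather than hard-coded. Cohort follow-up ends at the last
observed visit, with no distinction between disenrollment and death.
ICD-10 dialect differences (e.g. ICD-10-CM) and native Japanese claim
receipt code formats are out of scope; inputs are expected in the
package's documented CSV schema.
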