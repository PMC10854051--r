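Package: migrainepaths
Title: Treatment-Pattern Analysis of Migraine in Administrative Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds headache and migraine cohorts from longitudinal
    administrative claims tables, chains raw prescription claims into
    continuous-use episodes (drug eras) with a refill-gap rule, assigns
    ordinal treatment prescriptions (first through fourth), and detects
    three rule-based phenotypes of patients potentially not managed well
    by current therapy: triptan switching, prescription patterns
    suggestive of medication-overuse headache, and no decrease in acute
    drug use after starting preventive treatment. Ships a seeded
    synthetic-claims generator with planted ground-truth phenotypes so
    every pipeline stage can be validated against known labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    stats,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
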