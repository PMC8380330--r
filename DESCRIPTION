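Package: micecvr
Title: Sex-Specific Variability of Mouse Blood Parameters via
    Coefficient-of-Variation Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis pipeline for sex-specific phenotypic variability
    in strain-survey blood data of laboratory mice. Reads Mouse Phenome
    Database style per-animal or per-group tables, applies the selection
    criteria (inbred-type strains, untreated, 7-26 weeks of age, at least
    five animals per sex) and a CV > 0.5 outlier-exclusion rule, computes
    the coefficient-of-variation ratio female CV / (female CV + male CV)
    per strain data set, aggregates per parameter and per inbred-strain
    family, runs equal-split chi-squared tests and consistency checks, and
    ships a seeded synthetic-data generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
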