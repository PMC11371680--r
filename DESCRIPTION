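Package: cartpv
Title: Pharmacovigilance Signal Detection for CAR-T Pulmonary Adverse
    Events in FAERS-Format Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for disproportionality analysis of
    pulmonary adverse events after chimeric antigen receptor T-cell
    (CAR-T) therapy in spontaneous reporting data distributed in the FDA
    Adverse Event Reporting System (FAERS) quarterly ASCII format. Reads
    and validates "$"-delimited quarterly packages, applies the FDA
    case-level deduplication and deletion-list rules, extracts a CAR-T
    cohort via a product synonym dictionary and flags pulmonary events
    through a user-supplied MedDRA PT-to-SOC mapping, computes four
    signal-detection algorithms (reporting odds ratio, proportional
    reporting ratio with chi-squared, information component, and the
    empirical Bayes geometric mean closed form) with a joint signal
    rule, stratifies IC025 per product, and summarises time to onset,
    annual counts, demographics and case-fatality proportions. A seeded
    synthetic FAERS-format generator with planted signals, duplicates
    and deletion lists makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
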