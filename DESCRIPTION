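Package: nbsvar
Title: Variant Harvesting and ACMG/AMP Classification for Newborn-Screening
    Registry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the secondary analysis of longitudinal newborn-screening
    follow-up registries: harvest heterogeneously formatted genetic variant
    submissions from subject records, normalize HGVS and single-letter protein
    notation, validate reported reference residues against protein sequences,
    reconcile variants against ClinVar-style gene extracts, assign ACMG/AMP
    evidence criteria from longitudinal clinical data, combine criteria into
    clinical-significance classifications with the full combining-rule table,
    and re-audit classifications against a later database snapshot with a
    hypergeometric enrichment test. Includes a synthetic-cohort generator with
    planted ground truth so the whole pipeline is testable without access to
    restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
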