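Package: ctdash
Title: Audit Clinical Trial Registration and Reporting Transparency at Research Institutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semiautomated pipeline that audits registered clinical trials led
    by university medical centers against seven transparency practices:
    prospective registration, reporting of the trial registration number in the
    abstract and full text of results publications, publication links in the
    registry, summary-results reporting in the registry, timely reporting of
    results within two and five years of completion, and open-access status.
    Parses ClinicalTrials.gov- and DRKS-dialect registry exports, detects trial
    registration numbers with a configurable regular-expression inventory,
    applies each metric's denominator rule, summarises proportions with
    continuity-corrected Wilson confidence intervals, and renders a static
    per-institution dashboard. A seeded truth-first synthetic-cohort generator
    makes every pipeline stage testable without registry downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stringr,
    tibble,
    tidyr,
    vctrs,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
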