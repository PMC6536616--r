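Package: bmisturnover
Title: Investigator Turnover Phenotyping from FDA 1572 Submission Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds unique-investigator cohorts from Bioresearch Monitoring
    Information System (BMIS) style flat-file dumps of Form FDA 1572
    submissions, derives first- and second-submission gap times, classifies
    investigators into one-and-done, stop-and-go and stayer phenotypes via an
    empirical gap-time percentile cutoff, stratifies by U.S. versus non-U.S.
    location, and aggregates annual trend tables. Includes a seeded synthetic
    registry generator with ground truth and a window-censoring bias
    experiment, so the whole pipeline is testable without any FDA download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
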