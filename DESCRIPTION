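Package: sleepdep
Title: Wearable Sleep Features and Depression Severity in Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives nightly sleep metrics and 18 windowed sleep features
    (architecture, stability, quality, insomnia, hypersomnia) from
    wearable-device hypnogram sessions, applies cohort inclusion criteria,
    and estimates feature-depression associations with 2- and 3-level
    random-intercept linear mixed models, Wald z tests with
    Benjamini-Hochberg correction, and Spearman checks between the PHQ-8
    total and its sleep item. Includes a multi-site synthetic cohort
    generator with configurable depression-sleep couplings so the full
    pipeline and parameter-recovery studies run without access to any
    private cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    withr,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
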