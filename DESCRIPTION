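Package: agiscreen
Title: Age- and Sex-Stratified Genomic and Immune Profiling Screens for
    Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the genomic alteration landscape and tumor
    immune microenvironment of younger versus older cancer patients using
    comprehensive genomic and immune profiling (CGIP) data. Implements
    housekeeping-gene median-ratio normalization of targeted immune RNA-seq
    counts with percentile-rank signature scoring (TIGS, CP, CTAB), Firth
    penalized logistic regression with penalized likelihood-ratio trend
    tests over a sliding age threshold, gene-level and variant-level
    prevalence screens with Benjamini-Hochberg control, Cox proportional
    hazards and Kaplan-Meier immunotherapy survival analysis, and a
    synthetic cohort generator that emulates the joint structure of such
    data for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
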