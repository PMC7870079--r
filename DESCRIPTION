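Package: crclot
Title: Line-of-Therapy Derivation and Treatment-Sequence Analysis for
    Advanced Colorectal Cancer Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing systemic-therapy treatment lines for
    advanced colorectal cancer from longitudinal hospital claims.
    Implements rule-based cohort selection (first-line and
    early-recurrence populations and a second-line FOLFIRI plus
    antiangiogenic subpopulation), a line-of-therapy derivation algorithm
    built on a 28-day regimen-assembly window, a 180-day discontinuation
    gap, a new-drug rule with a biologic-addition exception, and a 60-day
    data-availability rule for completion and transition evaluability.
    Provides transition-rate and treatment-sequence summaries,
    second-line antiangiogenic prescription analytics, Kaplan-Meier,
    logistic and Cox stages, and a seeded synthetic claims generator with
    known ground truth for validating the whole pipeline.
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
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
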