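Package: hrphase
Title: Heart-Rate Phase Extraction and Circadian Disease Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a per-participant circadian heart-rate phase (HRP) from
    longitudinal wearable heart-rate streams by fitting a fixed 24-hour-period
    sine curve to a weekly 5-minute-binned profile, selects a goodness-of-fit
    threshold by a Youden-style retention index, and carries the phase forward
    through a genotype-phase association scan with robust standard errors, a
    phenome-wide association study over a hierarchical condition ontology,
    type 2 diabetes outcome models (logistic risk, maximum HbA1c processing,
    sex-stratified Cox proportional hazards on the age scale), and one-sample
    Mendelian randomization by two-stage residual inclusion with a
    participant-level bootstrap. A synthetic-cohort generator reproduces the
    genotype-to-phase-to-disease causal structure the analysis assumes, so the
    full pipeline is testable without access to controlled wearable or health
    record data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lmtest,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    minpack.lm,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
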