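Package: probank
Title: Clinical Oversampling in Patient-Reported Outcome Item-Bank Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying what happens to graded-response-model (GRM)
    item and person parameters when patient-reported-outcome (PRO) item banks
    are calibrated on samples enriched with clinical respondents. Provides a
    quasi-trait item-bank generator, latent-trait samplers for two population
    scenarios (distinct general/clinical distributions, and a single
    distribution split at a clinical cut-off), a GRM response simulator, a
    marginal maximum likelihood estimator (Bock-Aitkin EM) with single-group,
    multi-group and case-weighted variants, MAP latent-trait scoring with
    standard errors, parameter-recovery summaries on item and person sides,
    and a runner for the full two-scenario, three-fraction,
    proper-versus-improper calibration experiment.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
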