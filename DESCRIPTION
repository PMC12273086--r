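Package: psyews
Title: Transdiagnostic Early-Warning Score for Psychiatric Hospitalisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development and validation pipeline for a transdiagnostic
    early-warning score predicting 6-month psychiatric hospitalisation from
    longitudinal clinician-rated severity (CGI-S) and functioning (GAF)
    measurements. Provides cohort construction with 180-day measurement
    windows, severity and visit-to-visit instability (tRMSSD) predictors,
    Cox proportional-hazards modelling with organisation-level adjustment,
    optimism-corrected and external validation (discrimination, calibration,
    prevalence-repinned predictive values), subgroup and fairness evaluation,
    intervention-impact arithmetic, and a synthetic EHR-like data generator
    with known ground-truth hazards for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
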