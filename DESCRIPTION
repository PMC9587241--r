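Package: asthmaCMA
Title: ICS Adherence (CMA7), SABA Use and Asthma Outcomes from Primary-Care Prescription Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for routine-care prescription databases that derives
    inhaled-corticosteroid adherence as the continuous medication availability
    measure with carry-over (CMA7), short-acting beta-agonist (SABA) prescription
    counts, oral-corticosteroid course exacerbations and ACQ-5 self-reported
    asthma control for a primary-care asthma cohort, and models the association
    between adherence, SABA use and outcomes with random-intercept logistic
    regression (practice-level intraclass correlation on the latent scale).
    Includes a calibrated synthetic electronic-health-record generator with
    known ground truth so every stage can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
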