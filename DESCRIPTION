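Package: dbstability
Title: Test-Retest Reliability and Longitudinal Stability of Smartphone
    Digital Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for smartphone-based digital
    biomarker studies of Parkinson disease. Generates synthetic cohorts of
    repeated gait, balance, sustained-phonation and finger-tapping
    recordings with controllable variance components; extracts the
    accelerometer, voice and tapping feature families used in remote
    assessment batteries; and runs the full reliability battery:
    Mann-Whitney baseline screening with Cohen d effect sizes, redundancy
    filtering, ICC(1,1) test-retest reliability across time-lag and
    repetition pairing schemes, top-feature selection by median ICC, and
    mixed between/within repeated-measures ANOVA models of repetition,
    elapsed-time and medication effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal,
    e1071,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
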