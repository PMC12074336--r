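Package: plmwatch
Title: Non-Contact Periodic Limb Movement Monitoring from Ultrasonic Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for non-contact monitoring of
    periodic limb movement disorder (PLMD) with a ceiling-mounted array of six
    ultrasonic distance sensors sampled at 4 Hz. Provides closed-form
    calculators for sensor beam coverage, pipeline latency and prediction
    accuracy; a seeded synthetic sleep-session generator with posture
    schedules, limb-movement episodes and ground truth; a bounded capture FIFO
    with empty-bed and per-posture normalization and six-bit occupancy
    patterns; a from-scratch random forest sleep-posture classifier
    (bootstrap resampling, random feature subsets, fully grown unpruned trees,
    majority voting); and a limb-movement detector that flags per-second
    motion on the two lower-limb channels, extracts movement events, applies
    pose-change and constant-movement exclusions, and stages PLMD from the
    confirmed event series.
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
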