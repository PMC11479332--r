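Package: bedpose
Title: In-Bed Posture Detection from Bed-Reaction Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting a person's
    position in bed from the vertical forces measured by load cells under
    the four bed legs. Generates synthetic four-channel load-cell
    recordings for virtual cohorts holding a transverse-pelvic-angle (TPA)
    pose protocol, derives centre-of-mass and respiration-band signals,
    extracts a twelve-feature window representation, classifies posture
    with a two-phase hierarchical scheme (coarse left/supine/right, then
    per-side angular bins at 45, 30 and 15 degree precision) under
    leave-one-participant-out cross-validation with incremental learning,
    and provides the accompanying nonparametric model-comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    xgboost,
    e1071,
    nnet,
    rpart,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
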