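Package: floorgait
Title: Functional Gait Assessment from Ambient Floor Vibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects footstep-induced impulses in floor-vibration recordings,
    extracts symptom-based gait features (step time, cadence, left-right
    symmetry, initial-contact type) and signal-based features, maps 100-m run
    performance onto a normative functional scale for muscular dystrophy, and
    predicts functional stages with a hierarchical step-trace-person model.
    Includes a synthetic gait-vibration simulator with ground-truth
    annotations so the full pipeline can be exercised and validated without
    access to patient recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
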