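Package: rvskill
Title: Reliability Volume Metrics for Repetitive Motor-Skill Training
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the Reliability Volume (RV) metric for assessing
    motor-skill consistency across repetitive training sessions from 3D
    instrument trajectories. Given a standard (expert) path and a set of
    imitation repetitions, the package derives pointwise Euclidean
    deviations, a descending threshold ladder, cylindrical working-space
    volumes, and empirical reliability, yielding the (reliability, volume)
    curve. It tracks precision at fixed reliability across growing
    repetition counts, applies a fatigue-aware stopping rule based on
    reliability changes at a fixed volume, and provides a synthetic
    trajectory generator with known noise structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
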