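Package: wheelsprint
Title: Wheelchair Rugby Sprint Propulsion and Performance Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-step prediction of wheelchair-rugby sprint performance from
    wheelchair set-up. A calibrated planar linkage model of the trunk, upper
    arm and forearm predicts per-stroke hand contact and release angles on
    the wheel for a given seat height, seat depth, seat angle and tire
    pressure; a partial-least-squares regression maps set-up and propulsion
    kinematics to 5 m sprint time. Includes the L9 orthogonal test design
    with level-average analysis, per-athlete grid-search coefficient
    calibration, Welch/Bonferroni evaluation statistics, and a seeded
    synthetic-athlete generator so the whole pipeline can be exercised and
    tested without access to athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
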