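Package: gaitspeed
Title: Walking-Speed Estimation and Validation from Waist-Worn
    Tri-Axial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates walking speed from waist-worn tri-axial
    accelerometer recordings and validates candidate estimators against a
    1 Hz reference speed trace. Implements twelve speed-prediction
    algorithms (step-length and walk-ratio variants, an inverted-pendulum
    step-length model, linear and support vector regression on per-step
    features, and direct integration of antero-posterior acceleration),
    per-step feature extraction with peak-detection step counting,
    session pre-processing (inactivity detection, stream synchronization,
    boundary trimming, zero-phase Butterworth filtering), and an
    agreement framework based on Lin's concordance correlation
    coefficient, coverage probability, and Bland-Altman limits of
    agreement with cluster-bootstrap confidence intervals. A synthetic
    gait-session simulator with known per-step ground truth supports
    end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    rlang,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
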