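Package: stackbeat
Title: ECG Heartbeat Classification with Distance-Weighted KNN Ensembles
Version: 0.1.0
Authors@R:
    person("stackbeat", "maintainers", email = "maintainers@stackbeat.invalid",
           role = c("aut", "cre"))
Description: Tools for four-class (AAMI N/S/V/F) heartbeat classification from
    single-lead ECG: wavelet denoising, Pan-Tompkins QRS detection, fixed-window
    beat segmentation, fiducial-point delineation, a ten-feature set combining
    beat morphology with interval and amplitude measurements, min-max feature
    normalization, a distance-weighted k-nearest-neighbor classifier (DWKNN),
    a stacking ensemble of DWKNN base learners with cross-validated
    meta-features, and the per-class sensitivity/specificity/predictive-value
    evaluation calculus.  Includes a synthetic annotated-ECG generator so the
    full pipeline is testable without external databases, basic WFDB
    (.hea/.dat/.atr) record support, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
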