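Package: physioemo
Title: Subject-Independent Emotion Recognition from Peripheral Physiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for four-class (valence x arousal) emotion
    recognition from peripheral physiological signals: ECG, electrodermal
    activity (EDA) and skin temperature. Provides a class-conditioned
    synthetic signal generator with per-subject effects and sensor-brand
    domain shift, heart-rate-variability and skin-conductance feature
    extraction, an automatic feature-calibration model (per-subject G-means
    centroid profiles with Pearson-correlation matching and centroid-ward
    translation), and a cellular-neural-network classifier with echo-state
    random templates, Euler integration and a ridge-regression readout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
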