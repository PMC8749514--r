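Package: driverstate
Title: Wearable-Sensor Detection of Drowsy and Inattentive Driving
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Unsupervised detection of drowsy and inattentive (absent-minded)
    driving from body-worn sensors. Computes heart-rate-variability features
    from RR-interval series (time-domain indices plus Yule-Walker
    autoregressive spectral LF/HF power) and sub-window-difference motion
    features from wrist accelerometry, and monitors both with PCA-based
    multivariate statistical process control: Hotelling's T-squared on
    retained principal components with an empirical-percentile control limit
    fitted on normal driving only. A priority decision flow fuses
    body-movement, drowsiness and inattention detectors into a per-second
    driver-state timeline. Includes a seeded synthetic biosignal generator
    with ground-truth episodes and a sensitivity/specificity evaluation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
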