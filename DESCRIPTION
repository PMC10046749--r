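Package: earppg
Title: In-Ear Photoplethysmography Mental-Stress Detection Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting mental stress from in-ear
    photoplethysmography (PPG) recorded together with tri-axis acceleration.
    Provides artifact-aware preprocessing (IIR DC removal, Chebyshev type-II
    bandpass filtering, infrared/red channel fusion, and recursive-least-squares
    motion-artifact cancellation with correlation-based accelerometer reference
    selection), fixed-length segmentation with subject-disjoint train/test
    splits, generalized-Morse-wavelet scalogram images, a compact convolutional
    neural network for binary classification of the scalograms, and standard
    classification metrics with ROC/AUC. Because suitable public recordings are
    scarce, the package includes a seeded synthetic-signal generator that
    emulates condition-dependent pulse morphology, baseline wander, sensor
    noise, and acceleration-coupled motion artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
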