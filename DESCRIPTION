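Package: wristfall
Title: Wrist-Worn Accelerometer Fall Detection: Offline Study Pipeline and
    On-Device Detector Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating fall detectors that run on
    wrist-worn devices streaming triaxial sensor data at 50 Hz.  Provides a
    seeded generator of fall and activity-of-daily-living (ADL) recordings,
    CSV input/output in a per-sensor per-trial layout, frequency reduction,
    rolling-median filtering and vertical-acceleration projection, sliding
    window extraction with overlap-based Fall/ADL labeling, the
    low-computational FS-1 feature set (maximum, minimum, mean, variance)
    computed in batch or recursively one reading at a time, a from-scratch
    k-nearest-neighbour classifier with Euclidean distance plus SVM and
    decision-tree adapters, stratified k-fold cross-validation over an
    exhaustive (frequency, window size, algorithm, feature subset)
    configuration grid, and a simulator of the on-watch detector with
    sequential feature collection, a classification dead zone, a
    memory-capped dataset and a user-feedback learning loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
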