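Package: gazedwell
Title: Webcam Gaze Estimation and Dwell-Based Hierarchical Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating webcam-based gaze interfaces
    that use pupil-position ratios rather than precise point-of-regard.
    Includes iris segmentation and pupil-center detection from eye images
    via image moments, normalized horizontal/vertical gaze ratios with
    pilot-calibrated re-normalization, one-point calibration, five-zone
    gaze-direction classification around a central dead zone, a dwell-time
    two-stage cluster/item selection state machine with timeout and back
    navigation, and a simulation harness reproducing a three-factor
    (dead-zone size x viewing distance x dwell threshold) study design with
    task-completion-time and error-rate metrics. A synthetic-fixture module
    generates eye images with known iris geometry and gaze-ratio streams
    with fixation drift, jitter and blink dropouts, so the full pipeline is
    testable without a camera or human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
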