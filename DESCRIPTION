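Package: markerlift
Title: Keypoint-to-Marker Lifting and Kinematic Analysis for Markerless Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lifting sparse video keypoints to dense anatomical
    marker sets for markerless motion capture. Provides a synthetic data
    generator based on articulated skeleton models, the data-preparation
    pipeline (root-centering, height normalization, keypoint noise, rotation
    augmentation, per-subject splits), three sequence-regression enhancer
    architectures (linear, LSTM, transformer) with weighted-loss training and
    early stopping, model scaling and inverse kinematics for joint-angle
    estimation, evaluation protocols for kinematic accuracy and
    generalizability, and a torque-actuated planar tracking simulation with
    foot-ground contact for estimating ground reaction forces and joint
    moments. Reads and writes TRC and MOT/STO motion-capture text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    tibble,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
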