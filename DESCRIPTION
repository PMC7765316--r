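Package: trajheat
Title: Movement-Trajectory Heatmaps for IMU-Based Human Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts wearable inertial-sensor (IMU) streams and 3D body-point
    trajectories into 2D crossing-count heatmap images and classifies
    activities with recurrent neural networks. Implements sensor calibration
    and root normalization, a dead-reckoning drift diagnostic, sliding-window
    PCA flattening of vertex trajectories, supercover line rasterization into
    count heatmaps, label-preserving image augmentation, hand-written LSTM and
    convolutional-LSTM classifiers trained with Adam and early stopping, and
    leave-one-person-out evaluation with confidence intervals and confusion
    matrices. Ships a seeded synthetic motion simulator that emulates a
    multi-subject activity cohort so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
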