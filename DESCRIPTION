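Package: poseclass
Title: Exercise Classification from Single-Camera Pose Keypoint Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising rehabilitation exercises from the keypoint
    time series produced by single-camera pose-detection models. Provides a
    data model and readers for 33-landmark skeleton recordings, preprocessing
    (cubic-spline resampling, hip-centred translation and shoulder-plane
    rotation transforms, sliding-window segmentation), two segment
    classifiers (an engineered-feature linear support vector machine and a
    three-layer one-dimensional convolutional network trained with Adam),
    subject-grouped cross-validation with class-balanced accuracy, experiment
    harnesses for keypoint subsets, coordinate transforms, camera-angle
    robustness and training-set saturation, and a seeded synthetic
    skeleton-motion simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
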