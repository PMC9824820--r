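# poseclass

Classification of rehabilitation exercises from single-camera pose-detection
keypoint time series.

At-home adherence to physiotherapy programs is hard to measure objectively.
Modern pose-detection models (BlazePose and relatives) turn an ordinary
smartphone video into a time series of 33 body landmarks, each a vector
`K_i = (x, y, z, v)` of image coordinates, estimated depth and a visibility
score. `poseclass` implements the full analysis chain for recognising
*which* exercise is being performed from such recordings:

- **Data model & I/O** — 33-landmark skeleton sequences (CSV/JSON), dataset
  manifests, and the five standard keypoint subsets (all 33, the 22
  non-face landmarks, the 17 COCO landmarks, the 12 major joints, 8
  upper-body joints).
- **Preprocessing** — cubic-spline resampling to 25 Hz; body-centric
  coordinate transforms (translation to the hip midpoint
  `K_o = (K_lhip + K_rhip)/2`, and a per-frame rotation `R = (x̂, ŷ, ẑ)`
  whose x–y plane contains the shoulders and `K_o`); sliding-window
  segmentation (default 400-sample / 16 s windows, 50-sample / 2 s stride)
  and flattening to a `C × W` channel tensor per window (132 channels for
  the full landmark set).
- **Classifiers** — an engineered-feature baseline (11 summary features per
  channel: mean, median, absolute energy, std, variance, min, max,
  skewness, kurtosis, mean spectral energy, mean crossings) feeding a
  linear SVM with `C = 0.025`; and a three-layer 1D convolutional network
  (128/256/128 feature maps, kernels 8/5/3, batch norm + ReLU, global
  average pooling, L2 normalisation, dense softmax) trained with Adam
  (50 epochs, learning rate 0.005). The CNN — forward pass, analytic
  gradients and the Adam optimiser — is implemented in-package on top of
  BLAS matrix products and is gradient-checked in the test suite.
- **Evaluation** — subject-grouped 5-fold cross-validation (no person in
  both train and test), class-balanced accuracy with Student-t 95%
  confidence intervals, and harnesses for the keypoint-subset,
  coordinate-transform, camera-angle and training-saturation experiments,
  plus an exhaustive grid search.
- **Synthetic data** — a seeded simulator of multi-subject, multi-class,
  multi-viewpoint skeleton recordings (sinusoidal joint programs on a
  33-landmark template, orthographic camera with a yaw parameter,
  Gaussian keypoint noise with a 5× noisier depth channel, visibility
  dips for distant landmarks). It provides a fully reproducible stand-in
  for human-subject videos, with class structure designed so that every
  qualitative claim the pipeline makes can be verified end to end.

## Worked example

Simulate a 12-subject low-back dataset filmed from two camera angles,
preprocess into body-centric 4 s windows over the major joints, and run
subject-split cross-validation with both models:

```r
library(poseclass)

sim <- simulation_config(n_subjects = 12, duration_s = 32, seed = 5)
manifest <- generate_dataset("low_back", sim, "sim_data")

pipe <- pipeline_config(rate_hz = 25, window_s = 4, stride_s = 4,
                        transform = "translate_rotate",
                        keypoint_set = "major_12",
                        channels = c("x", "y", "z"))
folds <- make_folds(manifest, k = 5, seed = 1)

cnn <- cnn_config(feature_maps = c(64, 128, 64), epochs = 6, seed = 1)
crossval(manifest, pipe, cnn, folds = folds)
#> <cv_report> balanced accuracy 1.000 +/- 0.000 (5 folds)
#>    model=cnn_config, keypoint_set=major_12, transform=translate_rotate, channels=xyz, width=100

crossval(manifest, pipe, svm_config(), folds = folds)
#> <cv_report> balanced accuracy 1.000 +/- 0.000 (5 folds)
#>    model=svm_config, keypoint_set=major_12, transform=translate_rotate, channels=xyz, width=100
```

Both classifiers recover the seven simulated exercise classes perfectly on
held-out subjects: the simulator's classes are separable by construction,
so these runs validate the pipeline rather than estimate real-world
accuracy. The interesting behaviour appears under distribution shift —
train on one camera angle and test on the other (raw image coordinates,
no transform):

```r
ang <- run_angle_experiment(manifest, "none",
                            pipeline_config(rate_hz = 25, window_s = 4,
                                            stride_s = 4, transform = "none",
                                            keypoint_set = "major_12",
                                            channels = c("x", "y", "z")),
                            svm_config(), seed = 1)
ang$table
#>   stage transform test_angle      mean       ci95
#> 1     1      none        0.0 1.0000000 0.00000000
#> 2     1      none       67.5 0.4982143 0.05927679
#> 3     2      none        0.0 1.0000000 0.00000000
#> 4     2      none       67.5 1.0000000 0.00000000
```

Accuracy on the unseen 67.5° viewpoint collapses to ~0.50, and training on
both angles restores it — the motivation for either multi-angle training
or the body-centric transforms.

A thin command-line wrapper over the same functions is installed at
`inst/cli/poseclass.R` (subcommands `simulate`, `crossval`, `experiment`).

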