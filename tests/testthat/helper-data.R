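# Shared fixtures. Heavy objects (the simulated study dataset and the
# models trained on it) are built once on first use and cached for the
# whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixtures)) assign(key, build(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# a random but valid skeleton sequence
make_seq <- function(n = 20, rate = 30, seed = 1, subject = "S01",
                     label = "ex", side = "symmetric", angle = 0) {
  set.seed(seed)
  coords <- array(0, dim = c(n, 33, 4))
  coords[, , 1:3] <- rnorm(n * 33 * 3, sd = 0.3)
  coords[, , 4] <- runif(n * 33)
  skeleton_sequence(coords, rate = rate, subject = subject, label = label,
                    side = side, angle = angle, task = "low_back")
}

# --- demonstration-scale study dataset: 12 subjects, 7 low-back classes,
# two camera angles 67.5 degrees apart, 32 s records at 30 Hz
demo_sim_config <- function() {
  simulation_config(n_subjects = 12, duration_s = 32, seed = 5)
}

get_manifest <- function() {
  memo("manifest", function() {
    dir <- file.path(tempdir(), "poseclass-sim12")
    generate_dataset("low_back", demo_sim_config(), dir)
  })
}

# pipeline used for the end-to-end model runs: 4 s non-overlapping
# windows at 25 Hz, major joints, x/y/z channels
demo_pipeline <- function(transform = "translate_rotate") {
  pipeline_config(rate_hz = 25, window_s = 4, stride_s = 4,
                  transform = transform, keypoint_set = "major_12",
                  channels = c("x", "y", "z"))
}

# narrow, short-schedule CNN used for the end-to-end demonstrations
demo_cnn_config <- function(seed = 1) {
  cnn_config(feature_maps = c(64, 128, 64), epochs = 6, seed = seed)
}

get_wd <- function() {
  memo("wd", function() preprocess_dataset(get_manifest(), demo_pipeline()))
}

get_folds <- function() memo("folds", function() make_folds(get_manifest(), 5, 1))

# CNN subject-split 5-fold CV on the full two-angle dataset
get_cnn_cv <- function() {
  memo("cnn_cv", function() {
    crossval(get_manifest(), demo_pipeline(), demo_cnn_config(),
             k = 5, seed = 1, folds = get_folds())
  })
}

# camera-angle experiment (engineered-feature SVM, raw coordinates)
get_angle_experiment <- function() {
  memo("angle_exp", function() {
    run_angle_experiment(get_manifest(), "none",
                         demo_pipeline("none"), svm_config(),
                         k = 5, seed = 1)
  })
}

# training-saturation curve for the CNN, single camera angle
get_saturation <- function() {
  memo("saturation", function() {
    run_saturation_experiment(get_manifest(), sizes = c(2, 5, 9),
                              pipeline = demo_pipeline(),
                              model = demo_cnn_config(), reps = 1,
                              k = 5, seed = 1)
  })
}

# one converged CNN: trained on the fold-1 training subjects (both
# angles), with the held-out fold-1 windows for property checks
get_flagship <- function() {
  memo("flagship", function() {
    wd <- get_wd()
    fold_of <- unname(get_folds()[wd$groups])
    train <- subset_windows(wd, fold_of != 1)
    test <- subset_windows(wd, fold_of == 1)
    cfg <- demo_cnn_config()
    cfg$n_channels <- dim(wd$X)[1]
    model <- train_cnn(cfg, train)
    list(model = model, train = train, test = test)
  })
}

# tiny 5-subject single-angle dataset for cheap smoke tests
get_tiny_manifest <- function() {
  memo("tiny_manifest", function() {
    cfg <- simulation_config(n_subjects = 5, n_classes = 3,
                             duration_s = 10, camera_angles_deg = 0,
                             seed = 9)
    generate_dataset("low_back", cfg, file.path(tempdir(), "poseclass-tiny"))
  })
}

tiny_pipeline <- function(...) {
  pipeline_config(rate_hz = 25, window_s = 2, stride_s = 2,
                  keypoint_set = "major_12", channels = c("x", "y"), ...)
}
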