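#' Class-balanced accuracy
#'
#' The unweighted mean of per-class recall over the classes present in
#' `y_true`; robust to the class imbalance introduced by asymmetric
#' exercises (5 repetitions per side versus 10).
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same length).
#' @return Accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (!length(y_true)) stop("empty label vector")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Half-width of the 95% confidence interval across folds
#'
#' Student-t interval: `t(0.975, k-1) * sd / sqrt(k)`.
#'
#' @param x Per-fold scores.
#' @return Non-negative half-width (0 for a single fold).
#' @export
ci95_halfwidth <- function(x) {
  k <- length(x)
  if (k < 2L) return(0)
  qt(0.975, df = k - 1L) * sd(x) / sqrt(k)
}

#' Subject-grouped fold assignment
#'
#' Shuffles the subjects with the given seed and partitions them into `k`
#' folds as evenly as possible (earlier folds take the remainder), so that
#' no subject's windows ever appear in both the training and test side of
#' a fold. Reuse the returned assignment across experiment conditions to
#' keep folds identical.
#'
#' @param x A `dataset_manifest`, `windowed_dataset`, or character vector
#'   of subject ids.
#' @param k Number of folds (default 5).
#' @param seed Shuffling seed.
#' @return Named integer vector mapping subject id to fold index in
#'   `1..k`, of class `fold_split`.
#' @export
make_folds <- function(x, k = 5L, seed = 1L) {
  subjects <-
    if (is.character(x)) sort(unique(x))
    else if (inherits(x, "windowed_dataset")) sort(unique(x$groups))
    else sort(unique(x$subject))
  n <- length(subjects)
  if (n < k)
    stop("need at least k=", k, " subjects, got ", n)
  set.seed(seed)
  shuffled <- sample(subjects)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- rep(seq_len(k), times = sizes)
  structure(stats::setNames(assignment, shuffled), class = "fold_split")
}

# restrict a flattened all-landmark dataset to a keypoint set + channel
# subset without re-running preprocessing
select_channels <- function(wd, kset, channels = c("x", "y", "z", "v")) {
  if (is.character(kset)) kset <- keypoint_set(kset)
  channels <- AXES[AXES %in% channels]
  want <- as.vector(t(outer(kset$indices, channels,
                            function(k, a) paste0("k", k, "_", a))))
  idx <- match(want, wd$channel_names)
  if (anyNA(idx))
    stop("dataset does not contain channel ", want[which(is.na(idx))[1]])
  out <- wd
  out$X <- wd$X[idx, , , drop = FALSE]
  out$channel_names <- want
  out$keypoint_set <- kset$name
  out
}

# dispatch on model config class ----------------------------------------

fit_windows <- function(model_config, train_wd, train_features = NULL) {
  if (inherits(model_config, "svm_config")) {
    feats <- train_features %||% feature_matrix(train_wd)
    fit_svm(feats, train_wd$labels, model_config)
  } else if (inherits(model_config, "cnn_config")) {
    cfg <- model_config
    cfg$n_channels <- dim(train_wd$X)[1]
    cfg$n_classes <- nlevels(droplevels(train_wd$labels))
    train_cnn(cfg, train_wd$X, droplevels(train_wd$labels))
  } else stop("model config must be an svm_config or cnn_config")
}

predict_windows <- function(model, test_wd, test_features = NULL) {
  if (inherits(model, "poseclass_svm"))
    predict(model, test_features %||% feature_matrix(test_wd))
  else
    predict(model, test_wd$X)
}

score_fold <- function(model, test_wd, test_features = NULL) {
  pred <- predict_windows(model, test_wd, test_features)
  balanced_accuracy(test_wd$labels, pred)
}

new_cv_report <- function(per_fold, condition = list()) {
  structure(list(per_fold = per_fold, mean = mean(per_fold),
                 ci95 = ci95_halfwidth(per_fold), condition = condition),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cond <- paste(names(x$condition),
                vapply(x$condition, function(v)
                  paste(as.character(v), collapse = "+"), ""),
                sep = "=", collapse = ", ")
  cat(sprintf("<cv_report> balanced accuracy %.3f +/- %.3f (%d folds)\n",
              x$mean, x$ci95, length(x$per_fold)))
  if (nzchar(cond)) cat("  ", cond, "\n")
  invisible(x)
}

#' Subject-grouped k-fold cross-validation
#'
#' Preprocesses the manifest once (coordinate transforms and feature
#' extraction are per-record/per-window, so no information crosses the
#' fold boundary), then for each fold trains on the training subjects'
#' windows and scores class-balanced accuracy on the held-out subjects'
#' windows. Feature standardisation (SVM) and all model fitting happen
#' inside the fold on training data only.
#'
#' @param manifest A `dataset_manifest`.
#' @param pipeline A [pipeline_config()].
#' @param model An [svm_config()] or [cnn_config()].
#' @param k Number of folds (default 5).
#' @param seed Fold-shuffling seed.
#' @param folds Optional precomputed [make_folds()] assignment shared
#'   across conditions.
#' @param angles Optional camera-angle filter applied to the manifest.
#' @param condition Metadata list recorded in the report.
#' @return A `cv_report` with fields `per_fold`, `mean`, `ci95`,
#'   `condition`.
#' @export
crossval <- function(manifest, pipeline = pipeline_config(),
                     model = cnn_config(), k = 5L, seed = 1L,
                     folds = NULL, angles = NULL, condition = list()) {
  if (!is.null(angles)) manifest <- manifest[manifest$angle %in% angles, ]
  folds <- folds %||% make_folds(manifest, k, seed)
  wd <- preprocess_dataset(manifest, pipeline)
  feats <- if (inherits(model, "svm_config")) feature_matrix(wd) else NULL
  fold_of <- unname(folds[wd$groups])
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold_of != f
    te <- !tr
    train_wd <- subset_windows(wd, tr)
    test_wd <- subset_windows(wd, te)
    missing_cls <- setdiff(unique(as.character(test_wd$labels)),
                           unique(as.character(train_wd$labels)))
    if (length(missing_cls))
      warning("fold ", f, ": class(es) ",
              paste(missing_cls, collapse = ", "),
              " absent from training; scoring restricted to observed ",
              "recalls")
    m <- fit_windows(model, train_wd,
                     if (!is.null(feats)) feats[tr, , drop = FALSE])
    per_fold[f] <- score_fold(m, test_wd,
                              if (!is.null(feats))
                                feats[te, , drop = FALSE])
  }
  cond <- utils::modifyList(
    list(model = class(model)[1], keypoint_set = pipeline$keypoint_set,
         transform = pipeline$transform,
         channels = paste(pipeline$channels, collapse = ""),
         width = pipeline$width), condition)
  new_cv_report(per_fold, cond)
}

modify_pipeline <- function(cfg, ...) {
  upd <- list(...)
  for (nm in names(upd)) cfg[[nm]] <- upd[[nm]]
  if (any(c("window_s", "stride_s", "rate_hz") %in% names(upd))) {
    cfg$width <- as.integer(round(cfg$window_s * cfg$rate_hz))
    cfg$stride <- as.integer(round(cfg$stride_s * cfg$rate_hz))
  }
  cfg
}

#' Keypoint-combination experiment
#'
#' Evaluates the model over several keypoint subsets with identical
#' subject folds, using records from a single camera angle. Preprocessing
#' runs once on the full landmark set; each condition then selects its
#' channel subset.
#'
#' @param manifest A `dataset_manifest`.
#' @param sets Character vector of registered keypoint-set names.
#' @param pipeline,model,k,seed As in [crossval()].
#' @param angle Camera angle to keep (default: first in sorted order).
#' @return Named list of `cv_report`, one per set.
#' @export
run_keypoint_experiment <- function(manifest, sets = keypoint_set_names(),
                                    pipeline = pipeline_config(),
                                    model = cnn_config(), k = 5L,
                                    seed = 1L, angle = NULL) {
  for (s in sets) keypoint_set(s)  # validate names up front
  angle <- angle %||% sort(unique(manifest$angle))[1]
  manifest <- manifest[manifest$angle == angle, ]
  folds <- make_folds(manifest, k, seed)
  full <- modify_pipeline(pipeline, keypoint_set = "all_33",
                          channels = AXES)
  wd_full <- preprocess_dataset(manifest, full)
  fold_of <- unname(folds[wd_full$groups])
  reports <- list()
  for (s in sets) {
    wd <- select_channels(wd_full, s, pipeline$channels)
    feats <- if (inherits(model, "svm_config")) feature_matrix(wd) else NULL
    per_fold <- vapply(seq_len(k), function(f) {
      tr <- fold_of != f
      m <- fit_windows(model, subset_windows(wd, tr),
                       if (!is.null(feats)) feats[tr, , drop = FALSE])
      score_fold(m, subset_windows(wd, !tr),
                 if (!is.null(feats)) feats[!tr, , drop = FALSE])
    }, numeric(1))
    reports[[s]] <- new_cv_report(
      per_fold, list(model = class(model)[1], keypoint_set = s,
                     transform = pipeline$transform,
                     channels = paste(pipeline$channels, collapse = ""),
                     angle = angle))
  }
  reports
}

#' Camera-angle robustness experiment
#'
#' Stage 1 trains on the first camera angle only and scores the held-out
#' subjects separately on each angle; stage 2 trains on both angles and
#' scores both. Subject folds are identical in both stages and across
#' transforms.
#'
#' @param manifest A `dataset_manifest` with at least two angle ids.
#' @param transforms Coordinate transforms to evaluate.
#' @param pipeline,model,k,seed As in [crossval()].
#' @return List with `reports` (per stage/transform/test-angle
#'   `cv_report`s) and `table` (a summary data frame).
#' @export
run_angle_experiment <- function(manifest,
                                 transforms = c("none", "translate",
                                                "translate_rotate"),
                                 pipeline = pipeline_config(),
                                 model = cnn_config(), k = 5L, seed = 1L) {
  angles <- sort(unique(manifest$angle))
  if (length(angles) < 2L)
    stop("angle experiment needs at least two camera angles, got ",
         length(angles))
  a1 <- angles[1]; a2 <- angles[2]
  folds <- make_folds(manifest, k, seed)
  reports <- list()
  rows <- list()
  for (tr_name in transforms) {
    pipe <- modify_pipeline(pipeline, transform = tr_name)
    wd <- preprocess_dataset(manifest, pipe)
    feats <- if (inherits(model, "svm_config")) feature_matrix(wd) else NULL
    fold_of <- unname(folds[wd$groups])
    for (stage in 1:2) {
      train_angle_ok <-
        if (stage == 1L) wd$angles == as.character(a1) else rep(TRUE, n_windows(wd))
      scores <- list()
      for (f in seq_len(k)) {
        tr_idx <- fold_of != f & train_angle_ok
        m <- fit_windows(model, subset_windows(wd, tr_idx),
                         if (!is.null(feats))
                           feats[tr_idx, , drop = FALSE])
        for (ang in c(a1, a2)) {
          te_idx <- fold_of == f & wd$angles == as.character(ang)
          key <- as.character(ang)
          scores[[key]] <- c(scores[[key]],
                             score_fold(m, subset_windows(wd, te_idx),
                                        if (!is.null(feats))
                                          feats[te_idx, , drop = FALSE]))
        }
      }
      for (ang in c(a1, a2)) {
        rep_key <- sprintf("stage%d.%s.angle_%s", stage, tr_name, ang)
        rpt <- new_cv_report(scores[[as.character(ang)]],
                             list(model = class(model)[1], stage = stage,
                                  transform = tr_name, test_angle = ang,
                                  train_angles = if (stage == 1L) a1
                                                 else c(a1, a2)))
        reports[[rep_key]] <- rpt
        rows[[rep_key]] <- data.frame(stage = stage, transform = tr_name,
                                      test_angle = ang, mean = rpt$mean,
                                      ci95 = rpt$ci95)
      }
    }
  }
  list(reports = reports, table = do.call(rbind, c(rows,
                                                   make.row.names = FALSE)))
}

#' Training-saturation experiment
#'
#' For each requested training-set size, a seeded random subset of the
#' training subjects of each fold is used to train the model, which is
#' then scored on that fold's full held-out subjects; subsampled sizes are
#' redrawn `reps` times and averaged.
#'
#' @param manifest A `dataset_manifest`.
#' @param sizes Integer vector of training subject counts.
#' @param pipeline,model,k,seed As in [crossval()].
#' @param reps Redraws per size (default 3; a size equal to the full
#'   training fold is deterministic and run once).
#' @param angle Camera angle to keep (default: first in sorted order).
#' @return List with `table` (size, mean, ci95) and `per_fold` matrix
#'   (size x fold).
#' @export
run_saturation_experiment <- function(manifest, sizes,
                                      pipeline = pipeline_config(),
                                      model = cnn_config(), reps = 3L,
                                      k = 5L, seed = 1L, angle = NULL) {
  angle <- angle %||% sort(unique(manifest$angle))[1]
  manifest <- manifest[manifest$angle == angle, ]
  folds <- make_folds(manifest, k, seed)
  wd <- preprocess_dataset(manifest, pipeline)
  feats <- if (inherits(model, "svm_config")) feature_matrix(wd) else NULL
  fold_of <- unname(folds[wd$groups])
  min_pool <- min(vapply(seq_len(k), function(f) sum(folds != f),
                         integer(1)))
  if (any(sizes > min_pool))
    stop("training size ", max(sizes), " exceeds the smallest training ",
         "fold (", min_pool, " subjects)")
  per_fold <- matrix(0, length(sizes), k,
                     dimnames = list(as.character(sizes), NULL))
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    for (f in seq_len(k)) {
      pool <- names(folds)[folds != f]
      te_idx <- fold_of == f
      n_rep <- if (size == length(pool)) 1L else reps
      accs <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        set.seed(seed + 1000L * si + 10L * f + r)
        chosen <- sample(pool, size)
        tr_idx <- wd$groups %in% chosen
        m <- fit_windows(model, subset_windows(wd, tr_idx),
                         if (!is.null(feats))
                           feats[tr_idx, , drop = FALSE])
        accs[r] <- score_fold(m, subset_windows(wd, te_idx),
                              if (!is.null(feats))
                                feats[te_idx, , drop = FALSE])
      }
      per_fold[si, f] <- mean(accs)
    }
  }
  table <- data.frame(size = sizes,
                      mean = rowMeans(per_fold),
                      ci95 = apply(per_fold, 1L, ci95_halfwidth))
  list(table = table, per_fold = per_fold)
}

#' Exhaustive grid search over pipeline and model options
#'
#' Evaluates every combination of input channels, keypoint set, coordinate
#' transform, window width and (CNN only) learning rate with [crossval()]
#' on shared subject folds. Ties for the best mean balanced accuracy are
#' broken by enumeration order (channels, then keypoint set, then
#' transform, then width, then learning rate).
#'
#' @param manifest A `dataset_manifest`.
#' @param grid Named list of options; recognised names: `channels` (list
#'   of channel vectors), `keypoint_sets`, `transforms`, `widths`
#'   (samples), `lrs`.
#' @param pipeline,model,k,seed,angles As in [crossval()].
#' @return List with `results` (one row per combination, in enumeration
#'   order) and `best` (the winning row).
#' @export
grid_search <- function(manifest, grid, pipeline = pipeline_config(),
                        model = cnn_config(), k = 5L, seed = 1L,
                        angles = NULL) {
  channels <- grid$channels %||% list(pipeline$channels)
  ksets <- grid$keypoint_sets %||% pipeline$keypoint_set
  transforms <- grid$transforms %||% pipeline$transform
  widths <- grid$widths %||% pipeline$width
  lrs <- if (inherits(model, "cnn_config")) grid$lrs %||% model$lr else NA
  if (!is.null(angles)) manifest <- manifest[manifest$angle %in% angles, ]
  folds <- make_folds(manifest, k, seed)
  rows <- list()
  # enumeration order: channels, keypoint set, transform, width, lr
  for (ch in channels) for (ks in ksets) for (tr in transforms)
    for (w in widths) for (lr in lrs) {
      pipe <- modify_pipeline(pipeline, channels = AXES[AXES %in% ch],
                              keypoint_set = ks, transform = tr)
      pipe$width <- as.integer(w)
      mod <- model
      if (inherits(model, "cnn_config") && !is.na(lr)) mod$lr <- lr
      rpt <- crossval(manifest, pipe, mod, k = k, seed = seed,
                      folds = folds)
      rows[[length(rows) + 1L]] <-
        data.frame(channels = paste(pipe$channels, collapse = ""),
                   keypoint_set = ks, transform = tr, width = w,
                   lr = if (inherits(model, "cnn_config")) mod$lr else NA,
                   mean = rpt$mean, ci95 = rpt$ci95)
    }
  results <- do.call(rbind, c(rows, make.row.names = FALSE))
  best <- results[which.max(results$mean), , drop = FALSE]
  list(results = results, best = best)
}
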