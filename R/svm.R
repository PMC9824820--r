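#' Configuration for the engineered-feature linear SVM
#'
#' @param C Regularisation strength of the linear-kernel SVM
#'   (default 0.025).
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 0.025) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  structure(list(C = C, kernel = "linear"), class = "svm_config")
}

#' Fit the linear SVM on engineered features
#'
#' Features are standardised to zero mean and unit variance using
#' statistics computed from the training rows only (constant features are
#' centred and left unscaled), then a linear-kernel SVM with the
#' configured regularisation parameter is fitted.
#'
#' @param X An `N x p` feature matrix (e.g. from [feature_matrix()]) or a
#'   `windowed_dataset`, in which case features are computed internally.
#' @param y Per-row labels (taken from the dataset when `X` is a
#'   `windowed_dataset`).
#' @param config An [svm_config()].
#' @return Object of class `poseclass_svm`.
#' @export
fit_svm <- function(X, y = NULL, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  channel_names <- NULL
  if (inherits(X, "windowed_dataset")) {
    y <- y %||% X$labels
    channel_names <- X$channel_names
    X <- feature_matrix(X)
  }
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training labels must cover at least 2 classes")
  bad <- !is.finite(X)
  if (any(bad)) {
    j <- which(colSums(bad) > 0)[1]
    stop("non-finite value in feature '",
         colnames(X)[j] %||% paste0("f", j), "'")
  }
  center <- colMeans(X)
  scale <- apply(X, 2L, function(col) sqrt(mean((col - mean(col))^2)))
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fit <- e1071::svm(Xs, y, type = "C-classification", kernel = "linear",
                    cost = config$C, scale = FALSE)
  structure(list(kind = "svm", fit = fit, center = center, scale = scale,
                 feature_names = colnames(X), config = config,
                 class_names = levels(y), channel_names = channel_names),
            class = "poseclass_svm")
}

#' Predict exercise classes with a fitted SVM
#'
#' @param object A `poseclass_svm`.
#' @param newdata Feature matrix with the training columns, or a
#'   `windowed_dataset` (features are computed and checked against the
#'   training channel names).
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.poseclass_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "windowed_dataset")) {
    if (!is.null(object$channel_names) &&
        !identical(newdata$channel_names, object$channel_names))
      stop("shape error: dataset channels do not match the fitted model")
    newdata <- feature_matrix(newdata)
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center))
    stop("shape error: expected ", length(object$center),
         " features, got ", ncol(newdata))
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  predict(object$fit, Xs)
}

#' @export
print.poseclass_svm <- function(x, ...) {
  cat(sprintf(
    "<poseclass_svm> linear kernel, C=%g, %d features, %d classes\n",
    x$config$C, length(x$center), length(x$class_names)))
  invisible(x)
}
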