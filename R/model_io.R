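#' Save a trained classifier
#'
#' Writes the fitted state to `path` and a human-readable JSON sidecar
#' (`<path>.json`) recording the model kind, configuration, class names
#' and training channel names.
#'
#' @param model A `poseclass_cnn` or `poseclass_svm`.
#' @param path Output file for the fitted state.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("poseclass_cnn", "poseclass_svm")))
  saveRDS(model, path)
  side <- list(kind = model$kind, config = unclass(model$config),
               class_names = model$class_names,
               channel_names = model$channel_names)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a saved classifier
#'
#' @param path File written by [save_model()].
#' @param dataset Optional `windowed_dataset`; loading fails if its
#'   channel names do not match the model's training channels.
#' @return The restored model object.
#' @export
load_model <- function(path, dataset = NULL) {
  model <- readRDS(path)
  if (!inherits(model, c("poseclass_cnn", "poseclass_svm")))
    stop("file does not contain a poseclass model: ", path)
  if (!is.null(dataset) && !is.null(model$channel_names) &&
      !identical(dataset$channel_names, model$channel_names))
    stop("channel mismatch: model was trained on ",
         length(model$channel_names), " channels (",
         paste(head(model$channel_names, 3), collapse = ", "),
         ", ...) but the dataset provides ",
         length(dataset$channel_names))
  model
}
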