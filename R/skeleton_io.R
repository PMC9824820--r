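#' @importFrom stats splinefun qt sd rnorm runif median fft predict
#' @importFrom utils head tail
NULL

AXES <- c("x", "y", "z", "v")
N_LANDMARKS <- 33L
TASKS <- c("low_back", "shoulder")
SIDES <- c("left", "right", "symmetric")

#' BlazePose landmark names
#'
#' The 33-landmark full-body topology used throughout the package, in
#' 0-based index order (nose = 0, ..., right foot index = 32).
#'
#' @return Character vector of length 33.
#' @export
landmark_names <- function() {
  c("nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear", "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_pinky", "right_pinky",
    "left_index", "right_index", "left_thumb", "right_thumb",
    "left_hip", "right_hip", "left_knee", "right_knee",
    "left_ankle", "right_ankle", "left_heel", "right_heel",
    "left_foot_index", "right_foot_index")
}

# 0-based indices of commonly referenced landmarks
LM <- list(left_shoulder = 11L, right_shoulder = 12L,
           left_hip = 23L, right_hip = 24L)

#' Construct a skeleton keypoint time series
#'
#' A skeleton sequence holds one recording: an `n x 33 x 4` array of
#' keypoint coordinates (axes `x`, `y`, `z` and visibility `v`) plus the
#' sampling rate and recording metadata. `x` and `y` are image coordinates,
#' `z` is the pose model's depth estimate on the same scale as `x`, and `v`
#' is a visibility score in `[0, 1]`.
#'
#' @param coords Numeric array `n x 33 x 4` (frame, landmark, axis) or
#'   `n x 132` matrix in flattened channel order (`k0_x, k0_y, k0_z, k0_v,
#'   ...`).
#' @param rate Sampling rate in Hz. Ignored if `t` is given (the rate is
#'   then estimated from the median frame interval).
#' @param t Optional per-frame timestamps (seconds), strictly increasing.
#' @param subject,task,label,side,angle Recording metadata: subject id,
#'   task (`"low_back"` or `"shoulder"`), exercise class label, body side
#'   (`"left"`, `"right"` or `"symmetric"`) and camera-angle identifier.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(coords, rate = NULL, t = NULL,
                              subject = NA_character_, task = NA_character_,
                              label = NA_character_, side = NA_character_,
                              angle = NA) {
  if (is.matrix(coords)) {
    if (ncol(coords) != N_LANDMARKS * 4L)
      stop("flattened coords must have ", N_LANDMARKS * 4L, " columns, got ",
           ncol(coords))
    coords <- array(coords, dim = c(nrow(coords), 4L, N_LANDMARKS))
    coords <- aperm(coords, c(1L, 3L, 2L))
  }
  d <- dim(coords)
  if (length(d) != 3L || d[2] != N_LANDMARKS || d[3] != 4L)
    stop("coords must be an n x 33 x 4 array, got dims ",
         paste(d, collapse = " x "))
  n <- d[1]
  if (n < 1L) stop("a skeleton sequence needs at least one frame")
  if (is.null(t)) {
    if (is.null(rate) || !is.finite(rate) || rate <= 0)
      stop("rate must be a positive number when t is not supplied")
    t <- (seq_len(n) - 1L) / rate
  } else {
    if (length(t) != n) stop("t must have one timestamp per frame")
    if (n > 1L && any(diff(t) <= 0))
      stop("timestamps must be strictly increasing")
    rate <- if (n > 1L) 1 / median(diff(t)) else rate %||% 1
  }
  xyz <- coords[, , 1:3, drop = FALSE]
  if (!all(is.finite(xyz)))
    stop("non-finite coordinate value in x/y/z channels")
  vch <- coords[, , 4L, drop = FALSE]
  if (!all(is.finite(vch)) || any(vch < 0 | vch > 1))
    stop("visibility values must be finite and within [0, 1]")
  if (!is.na(task) && !task %in% TASKS)
    stop("task must be one of: ", paste(TASKS, collapse = ", "))
  if (!is.na(side) && !side %in% SIDES)
    stop("side must be one of: ", paste(SIDES, collapse = ", "))
  dimnames(coords) <- list(NULL, landmark_names(), AXES)
  structure(list(coords = coords, t = as.numeric(t), rate = rate,
                 subject = as.character(subject), task = as.character(task),
                 label = as.character(label), side = as.character(side),
                 angle = angle),
            class = "skeleton_sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf(
    "<skeleton_sequence> %d frames @ %.3g Hz (%.1f s)\n",
    n_frames(x), x$rate, diff(range(x$t))))
  cat(sprintf("  subject=%s task=%s label=%s side=%s angle=%s\n",
              x$subject, x$task, x$label, x$side, as.character(x$angle)))
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

# flattened 132-channel names in keypoint-major, axis-minor order (Eq. 3 style)
flat_channel_names <- function() {
  as.vector(t(outer(0:(N_LANDMARKS - 1L), AXES,
                    function(k, a) paste0("k", k, "_", a))))
}

# n x 132 matrix view of the coords array
flatten_coords <- function(seq) {
  m <- matrix(aperm(seq$coords, c(1L, 3L, 2L)), nrow = n_frames(seq))
  colnames(m) <- flat_channel_names()
  m
}

guess_format <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

#' Read a skeleton sequence from disk
#'
#' CSV files are wide, one row per frame, with header
#' `frame,t,k0_x,k0_y,k0_z,k0_v,...,k32_v`. A file may omit the whole `z`
#' or `v` column group, in which case depth defaults to 0 and visibility to
#' 1 (reported via a message); any other missing column is an error. JSON
#' files carry a metadata object alongside the per-frame arrays and restore
#' subject/task/label/side/angle.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @param subject,task,label,side,angle Metadata to attach (e.g. from a
#'   manifest row); for JSON these default to the values stored in the file.
#' @param quiet Suppress messages about defaulted channel groups.
#' @return A [skeleton_sequence()].
#' @export
read_sequence <- function(path, format = NULL, subject = NA, task = NA,
                          label = NA, side = NA, angle = NA, quiet = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    meta <- obj$metadata %||% list()
    pick <- function(arg, key) {
      if (length(arg) == 1 && is.na(arg)) meta[[key]] %||% NA else arg
    }
    coords <- if (is.matrix(obj$frames)) obj$frames
              else matrix(unlist(obj$frames), nrow = length(obj$t),
                          byrow = TRUE)
    sq <- skeleton_sequence(coords, t = as.numeric(obj$t),
                            rate = meta$rate %||% NULL,
                            subject = pick(subject, "subject"),
                            task = pick(task, "task"),
                            label = pick(label, "label"),
                            side = pick(side, "side"),
                            angle = pick(angle, "angle"))
    return(sq)
  }
  dt <- data.table::fread(path, showProgress = FALSE)
  want <- flat_channel_names()
  have <- names(dt)
  if (!"t" %in% have) stop("parse error in ", path, ": missing column t")
  missing <- setdiff(want, have)
  if (length(missing)) {
    miss_ax <- unique(sub("^k[0-9]+_", "", missing))
    # a wholly absent z or v group is tolerated with defaults
    for (ax in c("z", "v")) {
      grp <- grep(paste0("_", ax, "$"), want, value = TRUE)
      if (ax %in% miss_ax && all(grp %in% missing)) {
        fill <- if (ax == "z") 0 else 1
        for (cn in grp) dt[[cn]] <- fill
        if (!quiet)
          message("column group ", ax, " absent in ", basename(path),
                  "; defaulting to ", fill)
        missing <- setdiff(missing, grp)
      }
    }
    if (length(missing))
      stop("parse error in ", path, ": missing column ", missing[1])
  }
  coords <- as.matrix(dt[, want, with = FALSE])
  if (!all(is.finite(coords)))
    stop("validation error in ", path, ": non-finite coordinate")
  skeleton_sequence(coords, t = dt$t, subject = subject, task = task,
                    label = label, side = side, angle = angle)
}

#' Write a skeleton sequence to disk
#'
#' Inverse of [read_sequence()]; the round trip preserves coordinates to
#' better than 1e-9 in both formats, and metadata exactly for JSON.
#'
#' @param seq A `skeleton_sequence`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = NULL) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    m <- flatten_coords(seq)
    dt <- data.table::data.table(frame = seq_len(nrow(m)) - 1L, t = seq$t)
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, path, showProgress = FALSE)
  } else {
    obj <- list(
      metadata = list(subject = seq$subject, task = seq$task,
                      label = seq$label, side = seq$side, angle = seq$angle,
                      rate = seq$rate),
      t = seq$t,
      frames = unname(flatten_coords(seq)))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  }
  invisible(path)
}

KEYPOINT_SETS <- list(
  all_33 = 0:32,
  no_face_22 = 11:32,
  coco_17 = c(0L, 2L, 5L, 7L, 8L, 11:16, 23:28),
  major_12 = c(11:16, 23:28),
  upper_8 = c(11:16, 23L, 24L)
)

#' Named keypoint subsets
#'
#' Registry of the five landmark combinations used in the experiments:
#' the full 33-landmark topology, the 22 non-face landmarks, the 17-landmark
#' COCO set, the 12 major joints (shoulders, elbows, wrists, hips, knees,
#' ankles) and the 8 upper-body joints (shoulders, elbows, wrists, hips).
#'
#' @param name One of `"all_33"`, `"no_face_22"`, `"coco_17"`, `"major_12"`,
#'   `"upper_8"`.
#' @return Object of class `keypoint_set` with fields `name` and `indices`
#'   (0-based landmark indices).
#' @export
keypoint_set <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(KEYPOINT_SETS))
    stop("unknown keypoint set '", name, "'; valid names: ",
         paste(names(KEYPOINT_SETS), collapse = ", "))
  structure(list(name = name, indices = KEYPOINT_SETS[[name]]),
            class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set> %s (%d landmarks)\n", x$name,
              length(x$indices)))
  cat("  ", paste(landmark_names()[x$indices + 1L], collapse = ", "), "\n")
  invisible(x)
}

#' Names of the registered keypoint sets
#' @return Character vector.
#' @export
keypoint_set_names <- function() names(KEYPOINT_SETS)

MANIFEST_COLS <- c("path", "subject", "task", "label", "side", "angle")

#' Load a dataset manifest
#'
#' A manifest is a CSV with columns `path, subject, task, label, side,
#' angle`, one row per recording. Relative record paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest CSV.
#' @param check_files Verify that every referenced record file exists.
#' @return A `data.frame` of class `dataset_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- as.data.frame(data.table::fread(path, showProgress = FALSE,
                                        colClasses = list(
                                          character = c("path", "subject",
                                                        "task", "label",
                                                        "side"))))
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  as_manifest(df, check_files = check_files)
}

#' Validate a manifest data frame
#' @param df Data frame with the manifest columns.
#' @param check_files Verify referenced record files exist.
#' @return `df` with class `dataset_manifest`.
#' @export
as_manifest <- function(df, check_files = FALSE) {
  if (anyDuplicated(df$path))
    stop("validation error: duplicate record path in manifest: ",
         df$path[duplicated(df$path)][1])
  bad_task <- setdiff(unique(df$task), TASKS)
  if (length(bad_task))
    stop("validation error: unknown task value '", bad_task[1], "'")
  bad_side <- setdiff(unique(df$side), SIDES)
  if (length(bad_side))
    stop("validation error: unknown side value '", bad_side[1], "'")
  if (check_files) {
    gone <- !file.exists(df$path)
    if (any(gone))
      stop("manifest references missing file (entry ", which(gone)[1],
           "): ", df$path[which(gone)[1]])
  }
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Write a manifest to CSV
#' @param manifest A `dataset_manifest`.
#' @param path Output CSV path. Record paths are stored relative to the
#'   manifest directory when possible.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[, MANIFEST_COLS]
  base <- paste0(normalizePath(dirname(path), mustWork = FALSE), "/")
  df$path <- sub(base, "", df$path, fixed = TRUE)
  data.table::fwrite(df, path, showProgress = FALSE)
  invisible(path)
}

#' Enumerate subjects in a manifest
#' @param manifest A `dataset_manifest`.
#' @return Sorted character vector of distinct subject ids.
#' @export
manifest_subjects <- function(manifest) sort(unique(manifest$subject))
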