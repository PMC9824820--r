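#' Preprocessing pipeline configuration
#'
#' Bundles the tunable preprocessing constants. Defaults follow the
#' optimised settings used throughout the experiments: resampling to 25 Hz,
#' 16 s windows (400 samples) with a 2 s stride (50 samples) as overlap
#' augmentation, all 33 landmarks and all four channels.
#'
#' @param rate_hz Target sampling rate in Hz.
#' @param window_s Window width in seconds.
#' @param stride_s Window stride in seconds.
#' @param transform One of `"none"`, `"translate"` (hip-midpoint origin),
#'   `"translate_rotate"` (hip origin plus per-frame shoulder-plane
#'   rotation).
#' @param keypoint_set Name of a registered keypoint set
#'   (see [keypoint_set()]).
#' @param channels Subset of `c("x","y","z","v")`, kept in that order.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(rate_hz = 25, window_s = 16, stride_s = 2,
                            transform = c("none", "translate",
                                          "translate_rotate"),
                            keypoint_set = "all_33",
                            channels = c("x", "y", "z", "v")) {
  transform <- match.arg(transform)
  stopifnot(rate_hz > 0, window_s > 0, stride_s > 0)
  channels <- AXES[AXES %in% channels]
  if (!length(channels)) stop("channels must be a subset of x, y, z, v")
  ks <- keypoint_set(keypoint_set)  # validates the name
  structure(list(rate_hz = rate_hz, window_s = window_s, stride_s = stride_s,
                 width = as.integer(round(window_s * rate_hz)),
                 stride = as.integer(round(stride_s * rate_hz)),
                 transform = transform, keypoint_set = ks$name,
                 channels = channels),
            class = "pipeline_config")
}

#' Resample a skeleton sequence by cubic-spline interpolation
#'
#' Each of the 132 channels is interpolated independently with a cubic
#' (third-order) spline fitted to the original samples, then evaluated on a
#' uniform grid starting at the first timestamp with step `1/target_rate`;
#' no extrapolation occurs beyond the last timestamp. Visibility is clipped
#' back into `[0, 1]` after interpolation.
#'
#' @param seq A `skeleton_sequence` with at least 4 frames.
#' @param target_rate Target rate in Hz (default 25).
#' @return Resampled `skeleton_sequence`.
#' @export
resample_sequence <- function(seq, target_rate = 25) {
  stopifnot(inherits(seq, "skeleton_sequence"), target_rate > 0)
  n <- n_frames(seq)
  if (n < 4L)
    stop("cubic resampling needs at least 4 frames, got ", n)
  t0 <- seq$t[1]
  span <- seq$t[n] - t0
  new_t <- t0 + (0:floor(span * target_rate)) / target_rate
  old <- flatten_coords(seq)
  out <- matrix(0, length(new_t), ncol(old))
  for (j in seq_len(ncol(old))) {
    f <- splinefun(seq$t, old[, j], method = "fmm")
    out[, j] <- f(new_t)
  }
  vcols <- grep("_v$", flat_channel_names())
  out[, vcols] <- pmin(pmax(out[, vcols], 0), 1)
  skeleton_sequence(out, t = new_t, rate = target_rate,
                    subject = seq$subject, task = seq$task,
                    label = seq$label, side = seq$side, angle = seq$angle)
}

#' Body-centric orthonormal basis for one skeleton frame
#'
#' Computes the hip-midpoint origin and the rotation matrix used by the
#' `translate_rotate` transform. With hip-translated shoulders `s_l`,
#' `s_r`, let `u = s_r - s_l` and `c = (s_l + s_r)/2`; then
#' `x_hat = u/|u|`, `z_hat = (u x c)/|u x c|`, `y_hat = z_hat x x_hat`,
#' and `R` has rows `(x_hat, y_hat, z_hat)`. Both shoulders and the origin
#' then lie in the x-y plane of the rotated frame and `R` is right-handed.
#'
#' @param frame A `33 x 3` (or `33 x 4`) matrix of one frame's keypoints.
#' @return List with `origin` (hip midpoint), `R` (3x3 rotation, rows are
#'   the basis vectors) and `degenerate` (TRUE when the shoulders coincide
#'   or are collinear with the origin; `R` is then `NA`).
#' @export
frame_basis <- function(frame) {
  frame <- as.matrix(frame)[, 1:3, drop = FALSE]
  origin <- (frame[LM$left_hip + 1L, ] + frame[LM$right_hip + 1L, ]) / 2
  s_l <- frame[LM$left_shoulder + 1L, ] - origin
  s_r <- frame[LM$right_shoulder + 1L, ] - origin
  u <- s_r - s_l
  cmid <- (s_l + s_r) / 2
  nu <- sqrt(sum(u^2))
  w <- c(u[2] * cmid[3] - u[3] * cmid[2],
         u[3] * cmid[1] - u[1] * cmid[3],
         u[1] * cmid[2] - u[2] * cmid[1])
  nw <- sqrt(sum(w^2))
  if (nu < 1e-8 || nw < 1e-8)
    return(list(origin = origin, R = NA, degenerate = TRUE))
  xh <- u / nu
  zh <- w / nw
  yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
          zh[3] * xh[1] - zh[1] * xh[3],
          zh[1] * xh[2] - zh[2] * xh[1])
  list(origin = origin, R = rbind(xh, yh, zh, deparse.level = 0),
       degenerate = FALSE)
}

#' Apply a body-centric coordinate transform
#'
#' `"none"` returns the sequence unchanged. `"translate"` subtracts each
#' frame's hip midpoint from all keypoints. `"translate_rotate"`
#' additionally left-multiplies each keypoint's `(x,y,z)` by that frame's
#' shoulder-plane rotation (see [frame_basis()]), recomputed independently
#' for every frame. The visibility channel is never modified. A frame with
#' a degenerate basis reuses the previous frame's rotation (identity for a
#' degenerate first frame) and is reported via a warning.
#'
#' @param seq A `skeleton_sequence`.
#' @param transform `"none"`, `"translate"` or `"translate_rotate"`.
#' @return Transformed `skeleton_sequence`.
#' @export
apply_transform <- function(seq, transform = c("none", "translate",
                                               "translate_rotate")) {
  transform <- match.arg(transform)
  if (transform == "none") return(seq)
  coords <- seq$coords
  n <- dim(coords)[1]
  origin <- (coords[, LM$left_hip + 1L, 1:3, drop = FALSE] +
             coords[, LM$right_hip + 1L, 1:3, drop = FALSE]) / 2
  for (a in 1:3)
    coords[, , a] <- coords[, , a] - origin[, 1L, a]
  if (transform == "translate_rotate") {
    Rprev <- diag(3)
    degen <- integer(0)
    for (i in seq_len(n)) {
      fb <- frame_basis(matrix(coords[i, , 1:3], ncol = 3))
      if (fb$degenerate) {
        R <- Rprev
        degen <- c(degen, i)
      } else R <- fb$R
      coords[i, , 1:3] <- matrix(coords[i, , 1:3], ncol = 3) %*% t(R)
      Rprev <- R
    }
    if (length(degen))
      warning("degenerate shoulder basis in frame(s) ",
              paste(head(degen, 5), collapse = ", "),
              if (length(degen) > 5) ", ..." else "",
              "; previous frame's rotation reused")
  }
  out <- seq
  out$coords <- coords
  dimnames(out$coords) <- list(NULL, landmark_names(), AXES)
  out
}

#' Sliding-window segmentation
#'
#' Cuts a sequence into fixed-width windows starting at offsets
#' `0, stride, 2*stride, ...`; each window inherits the recording's
#' metadata. A sequence shorter than one window yields an empty list with
#' a warning (short records are dropped, not padded).
#'
#' @param seq A `skeleton_sequence`.
#' @param width Window width in samples (default 400 = 16 s at 25 Hz).
#' @param stride Window stride in samples (default 50 = 2 s at 25 Hz).
#' @return List of `skeleton_window` objects, each holding a
#'   `width x 33 x 4` coordinate slab plus metadata and the 0-based start
#'   offset.
#' @export
segment_sequence <- function(seq, width = 400L, stride = 50L) {
  stopifnot(inherits(seq, "skeleton_sequence"), width >= 1, stride >= 1)
  n <- n_frames(seq)
  if (n < width) {
    warning("sequence of ", n, " samples is shorter than the ", width,
            "-sample window; skipped")
    return(list())
  }
  starts <- seq.int(0L, n - width, by = stride)
  lapply(starts, function(s) {
    structure(list(coords = seq$coords[(s + 1L):(s + width), , ,
                                       drop = FALSE],
                   subject = seq$subject, task = seq$task, label = seq$label,
                   side = seq$side, angle = seq$angle, start = s),
              class = "skeleton_window")
  })
}

#' Flatten windows into a channels-by-time training tensor
#'
#' Assembles segmented windows into a `C x W x N` array whose channels are
#' ordered keypoint-major, axis-minor (`k_i x, k_i y, ...`) restricted to
#' the requested keypoint set and channel subset, together with per-window
#' labels, subject groups and camera angles.
#'
#' @param windows List of `skeleton_window` objects (from
#'   [segment_sequence()]), all of equal width.
#' @param kset A [keypoint_set()] or set name.
#' @param channels Subset of `c("x","y","z","v")`.
#' @return Object of class `windowed_dataset` with fields `X`
#'   (`C x W x N`), `labels` (factor), `groups`, `angles`, `sides`,
#'   `channel_names`, `width`.
#' @export
flatten_windows <- function(windows, kset = "all_33",
                            channels = c("x", "y", "z", "v")) {
  if (!length(windows)) stop("validation error: empty window list")
  if (is.character(kset)) kset <- keypoint_set(kset)
  channels <- AXES[AXES %in% channels]
  if (!length(channels)) stop("channels must be a subset of x, y, z, v")
  W <- dim(windows[[1]]$coords)[1]
  ki <- kset$indices + 1L
  ai <- match(channels, AXES)
  C <- length(ki) * length(ai)
  N <- length(windows)
  X <- array(NA_real_, dim = c(C, W, N))
  for (i in seq_len(N)) {
    w <- windows[[i]]$coords[, ki, ai, drop = FALSE]
    # (W, K, A) -> channels keypoint-major, axis-minor
    X[, , i] <- t(matrix(aperm(w, c(1L, 3L, 2L)), nrow = W))
  }
  channel_names <- as.vector(t(outer(kset$indices, channels,
                                     function(k, a) paste0("k", k, "_", a))))
  meta <- function(f) vapply(windows, function(w) as.character(w[[f]]), "")
  structure(list(X = X,
                 labels = factor(meta("label")),
                 groups = meta("subject"),
                 angles = meta("angle"),
                 sides = meta("side"),
                 channel_names = channel_names,
                 keypoint_set = kset$name,
                 width = W),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d windows, %d channels x %d samples\n",
    n_windows(x), dim(x$X)[1], x$width))
  cat(sprintf("  %d classes, %d subjects, %d angle(s)\n",
              nlevels(x$labels), length(unique(x$groups)),
              length(unique(x$angles))))
  invisible(x)
}

#' Number of windows in a windowed dataset
#' @param wd A `windowed_dataset`.
#' @return Integer count.
#' @export
n_windows <- function(wd) dim(wd$X)[3]

#' Subset a windowed dataset by window index
#' @param wd A `windowed_dataset`.
#' @param idx Integer or logical index over windows.
#' @return A `windowed_dataset` with the selected windows.
#' @export
subset_windows <- function(wd, idx) {
  out <- wd
  out$X <- wd$X[, , idx, drop = FALSE]
  out$labels <- wd$labels[idx]
  out$groups <- wd$groups[idx]
  out$angles <- wd$angles[idx]
  out$sides <- wd$sides[idx]
  out
}

#' Run the full preprocessing pipeline over a manifest
#'
#' Reads every record, resamples to the configured rate, applies the
#' configured coordinate transform, segments with the configured window and
#' stride, and flattens everything into one [flatten_windows()] dataset.
#' Records shorter than one window are skipped with a warning.
#'
#' @param manifest A `dataset_manifest`.
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-record progress messages.
#' @return A `windowed_dataset`.
#' @export
preprocess_dataset <- function(manifest, config = pipeline_config(),
                               quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_windows <- list()
  for (i in seq_len(nrow(manifest))) {
    e <- manifest[i, ]
    sq <- read_sequence(e$path, subject = e$subject, task = e$task,
                        label = e$label, side = e$side, angle = e$angle)
    sq <- resample_sequence(sq, config$rate_hz)
    sq <- apply_transform(sq, config$transform)
    w <- segment_sequence(sq, config$width, config$stride)
    if (!quiet)
      message(sprintf("%s: %d windows", basename(e$path), length(w)))
    all_windows <- c(all_windows, w)
  }
  flatten_windows(all_windows, config$keypoint_set, config$channels)
}
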