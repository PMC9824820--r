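# Neutral standing 33-landmark template in body-centred world units
# (y up, x to the subject's left, z toward the camera at angle 0; hip
# midpoint at the origin, stature ~1.5 units).
blazepose_template <- function() {
  m <- matrix(0, N_LANDMARKS, 3L,
              dimnames = list(landmark_names(), c("x", "y", "z")))
  set_lm <- function(name, x, y, z) m[name, ] <<- c(x, y, z)
  set_lm("nose", 0, 0.60, 0.08)
  eye <- 0.585; eye_y <- 0.635
  set_lm("left_eye_inner", 0.02, eye_y, 0.07)
  set_lm("left_eye", 0.035, eye_y, 0.065)
  set_lm("left_eye_outer", 0.05, eye_y, 0.06)
  set_lm("right_eye_inner", -0.02, eye_y, 0.07)
  set_lm("right_eye", -0.035, eye_y, 0.065)
  set_lm("right_eye_outer", -0.05, eye_y, 0.06)
  set_lm("left_ear", 0.07, 0.61, 0.02)
  set_lm("right_ear", -0.07, 0.61, 0.02)
  set_lm("mouth_left", 0.025, 0.565, 0.075)
  set_lm("mouth_right", -0.025, 0.565, 0.075)
  set_lm("left_shoulder", 0.18, 0.50, 0)
  set_lm("right_shoulder", -0.18, 0.50, 0)
  set_lm("left_elbow", 0.23, 0.27, 0.02)
  set_lm("right_elbow", -0.23, 0.27, 0.02)
  set_lm("left_wrist", 0.25, 0.05, 0.05)
  set_lm("right_wrist", -0.25, 0.05, 0.05)
  set_lm("left_pinky", 0.27, -0.02, 0.06)
  set_lm("right_pinky", -0.27, -0.02, 0.06)
  set_lm("left_index", 0.26, -0.03, 0.08)
  set_lm("right_index", -0.26, -0.03, 0.08)
  set_lm("left_thumb", 0.24, -0.02, 0.09)
  set_lm("right_thumb", -0.24, -0.02, 0.09)
  set_lm("left_hip", 0.10, 0, 0)
  set_lm("right_hip", -0.10, 0, 0)
  set_lm("left_knee", 0.11, -0.42, 0.03)
  set_lm("right_knee", -0.11, -0.42, 0.03)
  set_lm("left_ankle", 0.12, -0.82, 0)
  set_lm("right_ankle", -0.12, -0.82, 0)
  set_lm("left_heel", 0.12, -0.87, -0.04)
  set_lm("right_heel", -0.12, -0.87, -0.04)
  set_lm("left_foot_index", 0.13, -0.87, 0.10)
  set_lm("right_foot_index", -0.13, -0.87, 0.10)
  m
}

# left/right landmark partner, 0-based (midline landmarks map to
# themselves)
mirror_index <- function() {
  pairs <- rbind(c(1, 4), c(2, 5), c(3, 6), c(7, 8), c(9, 10), c(11, 12),
                 c(13, 14), c(15, 16), c(17, 18), c(19, 20), c(21, 22),
                 c(23, 24), c(25, 26), c(27, 28), c(29, 30), c(31, 32))
  map <- 0:32
  map[pairs[, 1] + 1L] <- pairs[, 2]
  map[pairs[, 2] + 1L] <- pairs[, 1]
  map
}

#' Define a synthetic exercise motion class
#'
#' A motion class is a set of per-landmark sinusoidal joint programs:
#' landmark trajectories are the template posture plus a baseline offset
#' plus `amp * sin(2*pi*freq*t + phase)` per axis. Programs are specified
#' for midline and left-side landmarks only; symmetric classes are
#' mirrored onto the right side automatically (x amplitude and offset
#' negated), while asymmetric classes keep the program on the active side.
#' Face, hand and foot landmarks automatically follow the nose, wrists and
#' ankles.
#'
#' @param name Exercise label.
#' @param programs Data frame with columns `landmark` (0-based index),
#'   `ax,ay,az` (amplitude, world units), `freq` (Hz, in (0.05, 2]),
#'   `phase` (radians) and optional `ox,oy,oz` baseline posture offsets.
#' @param side_mode `"symmetric"` or `"asymmetric"`.
#' @param body_region `"upper"`, `"lower"` or `"full"`.
#' @return Object of class `motion_class`.
#' @export
motion_class <- function(name, programs,
                         side_mode = c("symmetric", "asymmetric"),
                         body_region = c("full", "upper", "lower")) {
  side_mode <- match.arg(side_mode)
  body_region <- match.arg(body_region)
  for (col in c("ox", "oy", "oz"))
    if (is.null(programs[[col]])) programs[[col]] <- 0
  stopifnot(all(c("landmark", "ax", "ay", "az", "freq", "phase") %in%
                  names(programs)))
  if (any(programs$freq <= 0.05 | programs$freq > 2))
    stop("program frequencies must lie in (0.05, 2] Hz")
  if (all(abs(programs[, c("ax", "ay", "az")]) < 1e-12))
    stop("a motion class needs at least one nonzero amplitude")
  structure(list(name = name, programs = programs, side_mode = side_mode,
                 body_region = body_region),
            class = "motion_class")
}

prog <- function(landmark, ax, ay, az, freq, phase = 0,
                 ox = 0, oy = 0, oz = 0) {
  data.frame(landmark = landmark, ax = ax, ay = ay, az = az, freq = freq,
             phase = phase, ox = ox, oy = oy, oz = oz)
}

# Resolve a class's programs (defined on midline + left landmarks) for a
# given record side, then spread them to the attached face/hand/foot
# landmarks. Symmetric classes mirror left programs onto the right side
# with the x amplitude and offset negated; an asymmetric right-side record
# mirrors everything (including midline x) instead.
expand_programs <- function(cls, active_side = "left") {
  p <- cls$programs
  mir <- mirror_index()
  is_mid <- p$landmark == mir[p$landmark + 1L]
  flip_x <- function(rows) {
    rows$ax <- -rows$ax
    rows$ox <- -rows$ox
    rows
  }
  mirrored <- p[!is_mid, , drop = FALSE]
  mirrored$landmark <- mir[mirrored$landmark + 1L]
  mirrored <- flip_x(mirrored)
  if (cls$side_mode == "symmetric") {
    p <- rbind(p, mirrored)
  } else if (active_side == "right") {
    p <- rbind(flip_x(p[is_mid, , drop = FALSE]), mirrored)
  }
  attach_map <- list(`0` = list(idx = 1:10, f = 0.97),      # face <- nose
                     `15` = list(idx = c(17L, 19L, 21L), f = 1.05),
                     `16` = list(idx = c(18L, 20L, 22L), f = 1.05),
                     `27` = list(idx = c(29L, 31L), f = 1.02),
                     `28` = list(idx = c(30L, 32L), f = 1.02))
  extra <- list()
  for (key in names(attach_map)) {
    row <- p[p$landmark == as.integer(key), , drop = FALSE]
    if (!nrow(row)) next
    for (tgt in attach_map[[key]]$idx) {
      r <- row[1, ]
      r$landmark <- tgt
      f <- attach_map[[key]]$f
      r[c("ax", "ay", "az", "ox", "oy", "oz")] <-
        r[c("ax", "ay", "az", "ox", "oy", "oz")] * f
      extra[[length(extra) + 1L]] <- r
    }
  }
  do.call(rbind, c(list(p), extra))
}

#' Default synthetic motion classes for a task
#'
#' Seven exercise classes per task with distinct joint programs. The
#' low-back set (named after McKenzie-style movements) contains
#' lower-body-driven and full-body classes and two asymmetric classes;
#' the rotator-cuff shoulder set is upper-body dominated with four
#' asymmetric classes. Class names are synthetic stand-ins for the
#' protocols' exercise lists; the kinematics are invented sinusoid
#' programs, not biomechanical models.
#'
#' @param task `"low_back"` or `"shoulder"`.
#' @return Named list of 7 [motion_class()] objects.
#' @export
default_motion_classes <- function(task = c("low_back", "shoulder")) {
  task <- match.arg(task)
  cls <- if (task == "low_back") list(
    motion_class("standing_flexion", rbind(
      prog(0, 0, -0.26, 0.19, 0.14),
      prog(11, 0, -0.18, 0.14, 0.14),
      prog(13, 0, -0.23, 0.16, 0.14),
      prog(15, 0, -0.27, 0.18, 0.14)),
      "symmetric", "full"),
    motion_class("standing_extension", rbind(
      prog(0, 0, -0.07, -0.21, 0.18),
      prog(11, 0, -0.05, -0.15, 0.18),
      prog(13, 0.05, -0.02, -0.10, 0.18, oz = -0.05),
      prog(15, 0.03, 0.04, -0.12, 0.18, ox = -0.12, oy = 0.45, oz = -0.1)),
      "symmetric", "full"),
    motion_class("prone_press_up", rbind(
      prog(0, 0, 0.24, 0.06, 0.11, oy = -0.35, oz = 0.3),
      prog(11, 0, 0.19, 0.04, 0.11, oy = -0.3, oz = 0.25),
      prog(13, 0, 0.10, 0.02, 0.11, oy = -0.15, oz = 0.2),
      prog(23, 0, 0.04, 0.01, 0.11, oy = -0.05)),
      "symmetric", "upper"),
    motion_class("supine_knees_to_chest", rbind(
      prog(25, 0, 0.28, 0.16, 0.13, oy = 0.1),
      prog(27, 0, 0.32, 0.24, 0.13, oy = 0.25),
      prog(23, 0, 0.06, 0.03, 0.13)),
      "symmetric", "lower"),
    # pelvic_tilt and lumbar_rotation share an identical pelvis program
    # and differ only at the knees and ankles, so telling them apart
    # genuinely requires lower-body channels (as in real rolling/tilting
    # exercises, which look alike from the waist up)
    motion_class("pelvic_tilt", rbind(
      prog(23, 0, 0.08, 0.10, 0.16),
      prog(25, 0, 0.05, 0.06, 0.16)),
      "symmetric", "lower"),
    motion_class("side_glide", rbind(
      prog(0, 0.16, 0, 0, 0.20),
      prog(11, 0.17, 0, 0, 0.20),
      prog(23, 0.12, 0, 0, 0.20)),
      "asymmetric", "full"),
    motion_class("lumbar_rotation", rbind(
      prog(23, 0, 0.08, 0.10, 0.16),
      prog(24, 0, 0.08, 0.10, 0.16),
      prog(25, 0.22, 0, 0.11, 0.16, oy = 0.08),
      prog(27, 0.19, 0, 0.13, 0.16, oy = 0.2)),
      "asymmetric", "lower")
  ) else list(
    motion_class("pendulum", rbind(
      prog(15, 0.10, 0.02, 0.10, 0.45, oy = -0.05),
      prog(13, 0.06, 0.01, 0.06, 0.45)),
      "asymmetric", "upper"),
    motion_class("assisted_flexion", rbind(
      prog(15, 0, 0.31, 0.13, 0.10),
      prog(13, 0, 0.21, 0.09, 0.10),
      prog(11, 0, 0.05, 0.02, 0.10)),
      "symmetric", "upper"),
    motion_class("external_rotation", rbind(
      prog(15, 0.18, 0, 0.13, 0.15, oy = 0.25, oz = 0.1),
      prog(13, 0.04, 0, 0.03, 0.15)),
      "asymmetric", "upper"),
    motion_class("internal_rotation", rbind(
      prog(15, 0.10, -0.07, -0.12, 0.18, oy = 0.2, oz = 0.05),
      prog(13, 0.03, -0.02, -0.04, 0.18)),
      "asymmetric", "upper"),
    motion_class("scapular_retraction", rbind(
      prog(11, 0.05, 0.03, -0.09, 0.25),
      prog(13, 0.04, 0.01, -0.06, 0.25)),
      "symmetric", "upper"),
    motion_class("wall_slide", rbind(
      prog(15, 0, 0.30, 0.04, 0.18, oy = 0.35, oz = 0.15),
      prog(13, 0, 0.22, 0.03, 0.18, oy = 0.2, oz = 0.1),
      prog(11, 0, 0.06, 0.01, 0.18)),
      "symmetric", "upper"),
    motion_class("abduction", rbind(
      prog(15, 0.27, 0.21, 0, 0.13),
      prog(13, 0.17, 0.13, 0, 0.13),
      prog(11, 0.04, 0.03, 0, 0.13)),
      "asymmetric", "upper")
  )
  stats::setNames(cls, vapply(cls, `[[`, "", "name"))
}

#' Simulation configuration
#'
#' Study-protocol defaults: 7 classes, 60 s records at 30 Hz (half
#' duration for each side of an asymmetric exercise, mirroring 5
#' repetitions per side versus 10), two camera angles 67.5 degrees apart,
#' and pose-estimator-like Gaussian noise with 5x more high-frequency
#' noise on the depth (`z`) channel than on the image-plane channels.
#'
#' @param n_subjects Number of subjects.
#' @param n_classes Number of exercise classes to use (first `n` of the
#'   task's defaults).
#' @param reps_per_exercise Nominal repetitions per record (metadata;
#'   asymmetric sides get half the duration).
#' @param duration_s Record duration in seconds for symmetric exercises.
#' @param frame_rate_hz Camera frame rate.
#' @param camera_angles_deg Camera yaw angles in degrees, within
#'   `[0, 360)`.
#' @param noise_xy,noise_z Gaussian keypoint noise std dev in image units;
#'   `noise_z` must exceed `noise_xy`.
#' @param visibility_mean,visibility_sd Visibility score model; distant
#'   landmarks dip towards 0.5.
#' @param seed Master seed; all per-record seeds derive from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 12L, n_classes = 7L,
                              reps_per_exercise = 10L, duration_s = 60,
                              frame_rate_hz = 30,
                              camera_angles_deg = c(0, 67.5),
                              noise_xy = 0.005, noise_z = 0.025,
                              visibility_mean = 0.95,
                              visibility_sd = 0.03, seed = 1L) {
  stopifnot(n_subjects >= 1, n_classes >= 2, duration_s > 0,
            frame_rate_hz > 0, noise_xy >= 0)
  if (noise_z <= noise_xy && !(noise_z == 0 && noise_xy == 0))
    stop("noise_z must exceed noise_xy (the depth channel is noisier)")
  if (any(camera_angles_deg < 0 | camera_angles_deg >= 360))
    stop("camera angles must lie in [0, 360)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_classes = as.integer(n_classes),
                 reps_per_exercise = as.integer(reps_per_exercise),
                 duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 camera_angles_deg = camera_angles_deg,
                 noise_xy = noise_xy, noise_z = noise_z,
                 visibility_mean = visibility_mean,
                 visibility_sd = visibility_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Per-subject variation parameters
#'
#' Deterministically draws a subject's body-scale factor (+/-10%),
#' frequency factor (+/-15%), phase shift, small postural offset and image
#' placement offset from the master seed and subject index.
#'
#' @param subject_index 1-based subject number.
#' @param cfg A [simulation_config()].
#' @return List of subject parameters (`id`, `scale`, `freq_factor`,
#'   `phase`, `posture`, `img_offset`).
#' @export
subject_parameters <- function(subject_index, cfg = simulation_config()) {
  set.seed(cfg$seed + 7919L * as.integer(subject_index))
  list(id = sprintf("S%02d", subject_index),
       scale = runif(1, 0.9, 1.1),
       freq_factor = runif(1, 0.85, 1.15),
       phase = runif(1, 0, 2 * pi),
       posture = rnorm(3, 0, 0.02),
       img_offset = runif(2, -0.05, 0.05))
}

#' Generate one synthetic skeleton recording
#'
#' Builds the 3D world-frame skeleton for every frame from the template,
#' the class joint programs and the subject parameters; rotates the world
#' about the vertical axis by the camera angle; projects orthographically
#' to image coordinates (x right, y down, both offset to the image
#' centre; z kept as out-of-plane depth on the same scale); then adds
#' Gaussian noise (`noise_xy` on x/y, `noise_z` on z) and a visibility
#' score near 1 that dips for the most distant landmarks in each frame.
#' The world motion depends only on `seed` (not the camera angle), so two
#' angles of the same record are exact rigid rotations of one another
#' before noise.
#'
#' @param cls A [motion_class()].
#' @param subject A [subject_parameters()] list.
#' @param angle_deg Camera yaw in degrees, in `[0, 360)`.
#' @param cfg A [simulation_config()].
#' @param side `"symmetric"`, `"left"` or `"right"`.
#' @param seed Motion seed (per-record amplitude/phase jitter).
#' @param noise_seed Noise/visibility seed (defaults to `seed + 1`;
#'   varied per camera angle by [generate_dataset()]).
#' @return A [skeleton_sequence()].
#' @export
generate_record <- function(cls, subject, angle_deg, cfg,
                            side = "symmetric", seed = 1L,
                            noise_seed = seed + 1L) {
  if (!is.numeric(angle_deg) || angle_deg < 0 || angle_deg >= 360)
    stop("invalid camera angle: ", angle_deg)
  stopifnot(inherits(cls, "motion_class"))
  duration <- if (side == "symmetric") cfg$duration_s else cfg$duration_s / 2
  nf <- max(4L, as.integer(round(duration * cfg$frame_rate_hz)))
  t <- (seq_len(nf) - 1L) / cfg$frame_rate_hz
  base <- blazepose_template() * subject$scale
  base <- sweep(base, 2L, -subject$posture)
  progs <- expand_programs(cls, active_side = side)
  set.seed(seed)
  amp_jitter <- runif(1, 0.92, 1.08)
  phase_jitter <- runif(1, -0.3, 0.3)
  # world[frame, landmark, axis]
  world <- array(rep(base, each = nf), dim = c(nf, N_LANDMARKS, 3L))
  for (i in seq_len(nrow(progs))) {
    p <- progs[i, ]
    li <- p$landmark + 1L
    f <- min(max(p$freq * subject$freq_factor, 0.0501), 2)
    s <- sin(2 * pi * f * t + p$phase + subject$phase + phase_jitter)
    amp <- c(p$ax, p$ay, p$az) * subject$scale * amp_jitter
    off <- c(p$ox, p$oy, p$oz) * subject$scale
    for (a in 1:3)
      world[, li, a] <- world[, li, a] + off[a] + amp[a] * s
  }
  th <- angle_deg * pi / 180
  xr <- cos(th) * world[, , 1] + sin(th) * world[, , 3]
  zr <- -sin(th) * world[, , 1] + cos(th) * world[, , 3]
  yr <- world[, , 2]
  sc <- 0.45
  img_x <- 0.5 + subject$img_offset[1] + sc * xr
  img_y <- 0.5 + subject$img_offset[2] - sc * yr
  img_z <- sc * zr
  set.seed(noise_seed)
  if (cfg$noise_xy > 0) {
    img_x <- img_x + rnorm(length(img_x), 0, cfg$noise_xy)
    img_y <- img_y + rnorm(length(img_y), 0, cfg$noise_xy)
  }
  img_z <- img_z + rnorm(length(img_z), 0, cfg$noise_z)
  v <- matrix(pmin(pmax(rnorm(nf * N_LANDMARKS, cfg$visibility_mean,
                              cfg$visibility_sd), 0), 1),
              nf, N_LANDMARKS)
  n_far <- ceiling(0.1 * N_LANDMARKS)
  # most distant landmarks per frame = smallest out-of-plane depth
  depth_rank <- t(apply(img_z, 1L, rank, ties.method = "first"))
  far <- depth_rank <= n_far
  v[far] <- pmin(pmax(rnorm(sum(far), 0.5, 0.05), 0), 1)
  coords <- array(0, dim = c(nf, N_LANDMARKS, 4L))
  coords[, , 1] <- img_x; coords[, , 2] <- img_y
  coords[, , 3] <- img_z; coords[, , 4] <- v
  skeleton_sequence(coords, rate = cfg$frame_rate_hz, t = t,
                    subject = subject$id, task = NA,
                    label = cls$name, side = side, angle = angle_deg)
}

#' Generate a full synthetic exercise dataset
#'
#' Writes one record per subject x class x camera angle (x side for
#' asymmetric classes) through [write_sequence()], plus a `manifest.csv`,
#' and returns the loaded manifest. Generation is deterministic given the
#' task and configuration: world motion seeds do not depend on the camera
#' angle, noise seeds do.
#'
#' @param task `"low_back"` or `"shoulder"`.
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param classes Optional list of [motion_class()] objects overriding the
#'   task defaults.
#' @param format Record file format, `"csv"` or `"json"`.
#' @return A `dataset_manifest` (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(task = c("low_back", "shoulder"),
                             cfg = simulation_config(), out_dir,
                             classes = NULL, format = "csv") {
  task <- match.arg(task)
  classes <- classes %||% default_motion_classes(task)[seq_len(cfg$n_classes)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (si in seq_len(cfg$n_subjects)) {
    subj <- subject_parameters(si, cfg)
    for (ci in seq_along(classes)) {
      cls <- classes[[ci]]
      sides <- if (cls$side_mode == "asymmetric") c("left", "right")
               else "symmetric"
      for (di in seq_along(sides)) {
        motion_seed <- (cfg$seed + 100003L * si + 1009L * ci +
                        101L * di) %% .Machine$integer.max
        for (ai in seq_along(cfg$camera_angles_deg)) {
          ang <- cfg$camera_angles_deg[ai]
          sq <- generate_record(cls, subj, ang, cfg, side = sides[di],
                                seed = motion_seed,
                                noise_seed = motion_seed + 17L * ai)
          sq$task <- task
          fname <- sprintf("%s_%s_%s_a%02d.%s", subj$id, cls$name,
                           substr(sides[di], 1, 1), ai, format)
          write_sequence(sq, file.path(out_dir, fname), format)
          rows[[length(rows) + 1L]] <-
            data.frame(path = fname, subject = subj$id, task = task,
                       label = cls$name, side = sides[di], angle = ang)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  write_manifest(as_manifest(df), file.path(out_dir, "manifest.csv"))
  load_manifest(file.path(out_dir, "manifest.csv"))
}
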