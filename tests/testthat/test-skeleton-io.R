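test_that("CSV and JSON round trips preserve coordinates and metadata", {
  sq <- make_seq(n = 100, seed = 1, subject = "S07", label = "pendulum",
                 side = "left", angle = 67.5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_sequence(sq, csv)
  expect_equal(length(readLines(csv)), 101)  # header + one row per frame
  back <- read_sequence(csv, subject = "S07", label = "pendulum",
                        side = "left", angle = 67.5)
  expect_lt(max(abs(back$coords - sq$coords)), 1e-9)
  expect_equal(back$t, sq$t, tolerance = 1e-9)

  js <- withr::local_tempfile(fileext = ".json")
  write_sequence(sq, js)
  back <- read_sequence(js)
  expect_lt(max(abs(back$coords - sq$coords)), 1e-9)
  expect_identical(back$subject, "S07")
  expect_identical(back$label, "pendulum")
  expect_identical(back$side, "left")
  expect_equal(back$angle, 67.5)
})

test_that("malformed or degenerate record files are rejected with informative errors", {
  sq <- make_seq(n = 6, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_sequence(sq, csv)

  # a single missing coordinate column is named in the error
  dt <- data.table::fread(csv)
  dt[["k12_y"]] <- NULL
  bad <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, bad)
  expect_error(read_sequence(bad), "k12_y")

  # wholly absent z / v groups fall back to documented defaults
  dt <- data.table::fread(csv)
  for (cn in grep("_(z|v)$", names(dt), value = TRUE)) dt[[cn]] <- NULL
  defaulted <- withr::local_tempfile(fileext = ".csv")
  data.table::fwrite(dt, defaulted)
  got <- expect_message(read_sequence(defaulted, quiet = FALSE),
                        "defaulting")
  expect_true(all(got$coords[, , 3] == 0))
  expect_true(all(got$coords[, , 4] == 1))

  # non-finite coordinates and empty sequences never construct
  bad_coords <- array(0, c(3, 33, 4))
  bad_coords[2, 5, 1] <- Inf
  expect_error(skeleton_sequence(bad_coords, rate = 30), "non-finite")
  expect_error(skeleton_sequence(array(0, c(0, 33, 4)), rate = 30),
               "at least one frame")
  v_bad <- array(0, c(3, 33, 4)); v_bad[1, 1, 4] <- 1.5
  expect_error(skeleton_sequence(v_bad, rate = 30), "visibility")
})

test_that("keypoint registry has the documented sizes, subsets and mirror pairs", {
  expect_equal(keypoint_set("all_33")$indices, 0:32)
  expect_length(keypoint_set("coco_17")$indices, 17)
  m12 <- keypoint_set("major_12")$indices
  expect_true(all(keypoint_set("upper_8")$indices %in% m12))
  expect_true(all(m12 %in% keypoint_set("no_face_22")$indices))
  expect_true(all(keypoint_set("no_face_22")$indices %in% 0:32))
  # left/right mirror partners both present in the major-joint set
  for (pair in list(c(11, 12), c(13, 14), c(15, 16), c(23, 24),
                    c(25, 26), c(27, 28)))
    expect_true(all(pair %in% m12))
  expect_error(keypoint_set("torso_5"), "valid names")
  # registry is stable across calls
  expect_identical(keypoint_set("coco_17"), keypoint_set("coco_17"))
})

test_that("manifests validate entries and enumerate subjects", {
  man <- get_tiny_manifest()
  expect_s3_class(man, "dataset_manifest")
  expect_length(manifest_subjects(man), 5)

  df <- as.data.frame(man)
  dup <- rbind(df, df[1, ])
  expect_error(as_manifest(dup), "duplicate")
  bad_task <- df; bad_task$task[1] <- "knee"
  expect_error(as_manifest(bad_task), "unknown task")
  dangling <- df; dangling$path[2] <- "/nonexistent/file.csv"
  expect_error(as_manifest(dangling, check_files = TRUE), "entry 2")

  # a 21-subject manifest yields 21 distinct groups
  cfg <- simulation_config(n_subjects = 21, n_classes = 2, duration_s = 2,
                           camera_angles_deg = 0, seed = 3)
  man21 <- generate_dataset("shoulder", cfg,
                            file.path(tempdir(), "poseclass-21"))
  expect_length(manifest_subjects(man21), 21)
})
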