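test_that("default motion classes satisfy the task structure", {
  for (task in c("low_back", "shoulder")) {
    cls <- default_motion_classes(task)
    expect_length(cls, 7)
    expect_equal(anyDuplicated(names(cls)), 0)
    freqs <- unlist(lapply(cls, function(c) c$programs$freq))
    expect_true(all(freqs > 0.05 & freqs <= 2))
  }
  lb <- default_motion_classes("low_back")
  regions <- vapply(lb, `[[`, "", "body_region")
  expect_gte(sum(regions == "lower"), 2)
  expect_gte(sum(regions == "full"), 2)
  sh <- default_motion_classes("shoulder")
  expect_gte(sum(vapply(sh, `[[`, "", "side_mode") == "asymmetric"), 3)
})

test_that("noiseless records are exact sinusoids and generation is seed-deterministic", {
  cfg <- simulation_config(n_subjects = 2, duration_s = 8, noise_xy = 0,
                           noise_z = 0, seed = 4)
  cls <- motion_class("wave", prog(15, 0.1, 0.05, 0, 0.25),
                      "symmetric", "upper")
  subj <- subject_parameters(1, cfg)
  sq <- generate_record(cls, subj, 0, cfg, seed = 12)

  # programmed landmark: x(t) fits A*sin + B*cos + C to machine precision
  x <- sq$coords[, 16, 1]   # left wrist, 0-based index 15
  f <- min(max(0.25 * subj$freq_factor, 0.0501), 2)
  basis <- cbind(sin(2 * pi * f * sq$t), cos(2 * pi * f * sq$t), 1)
  resid <- x - basis %*% qr.solve(basis, x)
  expect_lt(max(abs(resid)), 1e-9)
  # unprogrammed landmark stays put
  expect_lt(diff(range(sq$coords[, 24, 1])), 1e-12)

  # same seeds -> bit-identical records
  sq2 <- generate_record(cls, subj, 0, cfg, seed = 12)
  expect_identical(sq$coords, sq2$coords)
  expect_error(generate_record(cls, subj, 400, cfg), "invalid camera angle")
})

test_that("the depth channel is noisier than the image-plane channels", {
  man <- get_manifest()
  sq <- read_sequence(man$path[1])
  dz <- apply(sq$coords[, , 3], 2, function(c) sd(diff(c)))
  dx <- apply(sq$coords[, , 1], 2, function(c) sd(diff(c)))
  expect_gt(mean(dz), mean(dx))
  # visibility stays in range with occasional dips
  expect_true(all(sq$coords[, , 4] >= 0 & sq$coords[, , 4] <= 1))
  expect_lt(min(sq$coords[, , 4]), 0.8)
})

test_that("dataset layout counts records per subject, class, angle and side", {
  sym <- lapply(1:7, function(i)
    motion_class(paste0("ex", i), prog(15, 0.1, 0.1, 0, 0.1 + i / 50),
                 "symmetric", "upper"))
  names(sym) <- paste0("ex", 1:7)
  cfg <- simulation_config(n_subjects = 12, duration_s = 2, seed = 6)
  man <- generate_dataset("shoulder", cfg,
                          file.path(tempdir(), "poseclass-sym"),
                          classes = sym)
  expect_equal(nrow(man), 12 * 7 * 2)  # all symmetric, two angles
  expect_length(manifest_subjects(man), 12)

  # an asymmetric class contributes one record per side per angle
  man2 <- get_tiny_manifest()
  asym <- names(which(vapply(default_motion_classes("low_back")[1:3],
                             `[[`, "", "side_mode") == "asymmetric"))
  if (length(asym))
    for (a in asym)
      expect_setequal(unique(man2$side[man2$label == a]),
                      c("left", "right"))
})

test_that("two camera angles of one record are the same motion seen from different viewpoints", {
  cfg <- simulation_config(n_subjects = 1, duration_s = 8, noise_xy = 0,
                           noise_z = 0, seed = 8)
  cls <- default_motion_classes("low_back")$standing_flexion
  subj <- subject_parameters(1, cfg)
  a <- generate_record(cls, subj, 0, cfg, seed = 5, noise_seed = 50)
  b <- generate_record(cls, subj, 67.5, cfg, seed = 5, noise_seed = 51)
  ca <- apply_transform(a, "translate_rotate")
  cb <- apply_transform(b, "translate_rotate")
  expect_lt(max(abs(ca$coords[, , 1:3] - cb$coords[, , 1:3])), 1e-6)
})
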