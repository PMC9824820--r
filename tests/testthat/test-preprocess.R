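test_that("cubic resampling preserves constants, sines and cubics", {
  # constant channels come back exactly
  sq <- make_seq(n = 50, rate = 30, seed = 1)
  sq$coords[, , 1:3] <- 0.25
  rs <- resample_sequence(sq, 25)
  expect_lt(max(abs(rs$coords[, , 1:3] - 0.25)), 1e-9)

  # 1 Hz sine sampled at 50 Hz, resampled to 25 Hz, against the analytic
  # curve
  n <- 201
  t <- (0:(n - 1)) / 50
  sq <- make_seq(n = n, rate = 50, seed = 2)
  sq$coords[, 1, 1] <- sin(2 * pi * t)
  rs <- resample_sequence(sq, 25)
  expect_lt(max(abs(rs$coords[, 1, 1] - sin(2 * pi * rs$t))), 1e-3)

  # polynomials up to degree 3 are reproduced on the interior
  sq$coords[, 2, 2] <- 0.3 - 0.2 * t + 0.05 * t^2 + 0.01 * t^3
  rs <- resample_sequence(sq, 25)
  interior <- rs$t > 0.5 & rs$t < max(t) - 0.5
  expect_lt(max(abs(rs$coords[interior, 2, 2] -
                      (0.3 - 0.2 * rs$t[interior] +
                         0.05 * rs$t[interior]^2 +
                         0.01 * rs$t[interior]^3))), 1e-8)

  expect_error(resample_sequence(make_seq(n = 3), 25), "at least 4")
})

test_that("the shoulder-plane basis is orthonormal, right-handed and correctly anchored", {
  # hip midpoint arithmetic
  frame <- matrix(0, 33, 3)
  frame[24, ] <- c(2, 4, 0)   # left hip (0-based index 23)
  frame[25, ] <- c(4, 6, 2)   # right hip (0-based index 24)
  frame[12, ] <- c(2, 10, 1)
  frame[13, ] <- c(4, 10, 1)
  fb <- frame_basis(frame)
  expect_equal(fb$origin, c(3, 5, 1))

  # canonical pose: shoulders parallel to x, torso up y -> identity
  canon <- matrix(0, 33, 3)
  canon[24, ] <- c(-0.1, 0, 0); canon[25, ] <- c(0.1, 0, 0)
  canon[12, ] <- c(-0.18, 0.5, 0); canon[13, ] <- c(0.18, 0.5, 0)
  fb <- frame_basis(canon)
  expect_lt(max(abs(fb$R - diag(3))), 1e-9)

  # random valid frames: orthonormal, right-handed, shoulders in-plane
  set.seed(5)
  for (i in 1:20) {
    frame <- matrix(rnorm(99), 33, 3)
    fb <- frame_basis(frame)
    if (fb$degenerate) next
    expect_lt(max(abs(fb$R %*% t(fb$R) - diag(3))), 1e-9)
    expect_equal(det(fb$R), 1, tolerance = 1e-9)
    for (sh in c(12, 13)) {
      rotated <- fb$R %*% (frame[sh, ] - fb$origin)
      expect_lt(abs(rotated[3]), 1e-9)
    }
  }

  # coincident shoulders are flagged as degenerate
  canon[13, ] <- canon[12, ]
  expect_true(frame_basis(canon)$degenerate)
})

test_that("coordinate transforms satisfy their defining constraints", {
  sq <- make_seq(n = 40, seed = 6)
  expect_identical(apply_transform(sq, "none"), sq)

  tr <- apply_transform(sq, "translate")
  hips <- (tr$coords[, 24, 1:3] + tr$coords[, 25, 1:3]) / 2
  expect_lt(max(abs(hips)), 1e-9)
  # translation is idempotent
  tr2 <- apply_transform(tr, "translate")
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-9)

  rot <- apply_transform(sq, "translate_rotate")
  # both shoulders end up in the x-y plane every frame
  expect_lt(max(abs(rot$coords[, 12:13, 3])), 1e-9)
  # visibility is bit-exact through every mode
  expect_identical(rot$coords[, , 4], sq$coords[, , 4])
  expect_identical(tr$coords[, , 4], sq$coords[, , 4])
})

test_that("windows inherit metadata and flattening follows the channel order", {
  sq <- make_seq(n = 120, seed = 7, subject = "S03", label = "abduction",
                 side = "right", angle = 45)
  expect_warning(none <- segment_sequence(make_seq(n = 399, seed = 1),
                                          400, 50), "shorter")
  expect_length(none, 0)

  wins <- segment_sequence(sq, 50, 25)
  expect_equal(vapply(wins, `[[`, 0, "start"), c(0, 25, 50))
  expect_true(all(vapply(wins, `[[`, "", "subject") == "S03"))

  wd <- flatten_windows(wins, "major_12", c("x", "y"))
  expect_equal(dim(wd$X), c(24L, 50L, 3L))
  expect_equal(wd$channel_names[1:4], c("k11_x", "k11_y", "k12_x", "k12_y"))
  # channel content matches the source array
  expect_equal(wd$X[1, , 2], sq$coords[26:75, 12, 1])
  expect_equal(wd$X[2, , 1], sq$coords[1:50, 12, 2])

  wd4 <- flatten_windows(wins, "coco_17", c("x", "y", "z", "v"))
  expect_equal(dim(wd4$X)[1], 68L)
  expect_error(flatten_windows(list(), "all_33"), "empty")
})
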