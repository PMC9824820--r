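test_that("closed-form feature values on simple channels", {
  # constant channel: location features equal the constant, spreads vanish
  W <- 400
  win <- matrix(5, 1, W)
  f <- compute_features(win, "c")
  expect_equal(unname(f["c.mean"]), 5)
  expect_equal(unname(f["c.median"]), 5)
  expect_equal(unname(f["c.min"]), 5)
  expect_equal(unname(f["c.max"]), 5)
  expect_equal(unname(f["c.std"]), 0)
  expect_equal(unname(f["c.var"]), 0)
  expect_equal(unname(f["c.abs_energy"]), 400 * 25)
  expect_equal(unname(f["c.skew"]), 0)   # zero-variance convention
  expect_equal(unname(f["c.kurt"]), 0)
  expect_equal(unname(f["c.mean_crossings"]), 0)

  # alternating +-1 crosses its mean between every pair of samples
  alt <- matrix(rep(c(1, -1), 20), 1)
  f <- compute_features(alt, "a")
  expect_equal(unname(f["a.mean_crossings"]), 39)

  expect_error(compute_features(matrix(1, 1, 3)), "at least 4")
})

test_that("feature matrix agrees with per-window computation and names features", {
  sq <- make_seq(n = 60, seed = 9)
  wd <- flatten_windows(segment_sequence(sq, 20, 20), "upper_8",
                        c("x", "z"))
  fm <- feature_matrix(wd)
  expect_equal(dim(fm), c(3L, 11L * 16L))
  for (i in seq_len(3))
    expect_equal(fm[i, ], compute_features(wd$X[, , i], wd$channel_names),
                 tolerance = 1e-12)
  expect_true("k11_x.mean_spec_energy" %in% colnames(fm))
})
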