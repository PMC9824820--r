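test_that("the linear SVM fits separable features, standardises on training data only, and is deterministic", {
  set.seed(21)
  X <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 4), 50))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 50)
  m <- fit_svm(X, y, svm_config())
  expect_equal(as.character(predict(m, X)), y)

  # training standardisation: zero mean, unit (population) variance
  Xs <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  expect_lt(max(abs(colMeans(Xs))), 1e-9)
  expect_equal(apply(Xs, 2, function(c) sqrt(mean((c - mean(c))^2))),
               c(f1 = 1, f2 = 1), tolerance = 1e-9)

  # refitting with the same data gives identical predictions
  m2 <- fit_svm(X, y, svm_config())
  set.seed(99); Xnew <- matrix(rnorm(40, 2), 20, 2,
                               dimnames = list(NULL, c("f1", "f2")))
  expect_identical(predict(m, Xnew), predict(m2, Xnew))

  expect_error(fit_svm(X, rep("a", 100)), "at least 2 classes")
  Xbad <- X; Xbad[3, 2] <- NaN
  expect_error(fit_svm(Xbad, y), "f2")
})

test_that("CNN training is seeded, descends, and nails separable data", {
  # three easily separable synthetic channel patterns
  set.seed(31)
  N <- 60
  X <- array(rnorm(4 * 30 * N, sd = 0.1), c(4, 30, N))
  y <- rep(c("s1", "s2", "s3"), length.out = N)
  tt <- seq_len(30) / 30
  for (i in seq_len(N)) {
    cls <- match(y[i], c("s1", "s2", "s3"))
    X[cls, , i] <- X[cls, , i] + sin(2 * pi * cls * tt)
  }
  cfg <- cnn_config(n_classes = 3, feature_maps = c(16, 24, 16),
                    epochs = 12, seed = 2)
  m <- train_cnn(cfg, X, y)
  expect_lt(tail(m$history, 1), m$history[1])  # descent sanity
  expect_gte(balanced_accuracy(y, predict(m, X)), 0.99)

  # same seed twice: identical first-epoch loss and predictions
  m2 <- train_cnn(cfg, X, y)
  expect_identical(m$history[1], m2$history[1])
  expect_identical(predict(m, X), predict(m2, X))

  # probability argmax equals the returned label; permutation equivariance
  P <- predict(m, X, type = "prob")
  expect_identical(as.character(predict(m, X)),
                   rownames(P)[apply(P, 2, which.max)])
  perm <- sample(N)
  expect_identical(predict(m, X[, , perm]), predict(m, X)[perm])

  expect_error(train_cnn(cfg, X, rep("s1", N)), "at least 2 classes")
  expect_error(train_cnn(cfg, X[, 1:5, ], y), "largest kernel")
  expect_error(predict(m, X[1:3, , ]), "shape error")
})

test_that("a converged CNN generalises across subjects and tolerates temporal shifts", {
  fl <- get_flagship()
  # held-out subjects: both models should recover the classes
  expect_gte(balanced_accuracy(fl$test$labels,
                               predict(fl$model, fl$test)), 0.9)

  # global average pooling: a modest circular time shift (up to half a
  # window) rarely changes the predicted label
  X <- fl$test$X
  W <- dim(X)[2]
  base_pred <- predict(fl$model, X)
  set.seed(41)
  shifts <- sample(1:(W %/% 2), dim(X)[3], replace = TRUE)
  Xs <- X
  for (i in seq_len(dim(X)[3]))
    Xs[, , i] <- X[, c((shifts[i] + 1):W, 1:shifts[i]), i]
  changed <- mean(predict(fl$model, Xs) != base_pred)
  expect_lt(changed, 0.05)
})

test_that("the engineered-feature SVM matches the CNN on the simulated study data", {
  rpt <- crossval(get_manifest(), demo_pipeline(), svm_config(),
                  k = 5, seed = 1, folds = get_folds())
  expect_length(rpt$per_fold, 5)
  expect_gte(rpt$mean, 0.9)
})

test_that("model artifacts round-trip through disk and reject mismatched channels", {
  fl <- get_flagship()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fl$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path, dataset = fl$test)
  expect_identical(predict(back, fl$test), predict(fl$model, fl$test))

  other <- flatten_windows(segment_sequence(make_seq(n = 30, seed = 2),
                                            10, 10), "upper_8", "x")
  expect_error(load_model(path, dataset = other), "channel mismatch")
})
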