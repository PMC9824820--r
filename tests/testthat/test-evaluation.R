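test_that("balanced accuracy equals the confusion-matrix oracle", {
  expect_equal(balanced_accuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  # recalls 1.0 and 0.5 average to 0.75
  expect_equal(balanced_accuracy(c("a", "a", "b", "b"),
                                 c("a", "a", "b", "a")), 0.75)
  # always predicting one of 7 balanced classes scores 1/7
  y <- rep(letters[1:7], each = 10)
  expect_equal(balanced_accuracy(y, rep("a", 70)), 1 / 7)
  expect_error(balanced_accuracy(character(0), character(0)), "empty")

  set.seed(13)
  for (i in 1:50) {
    y_true <- sample(letters[1:4], 40, replace = TRUE)
    y_pred <- sample(letters[1:5], 40, replace = TRUE)
    expect_equal(balanced_accuracy(y_true, y_pred),
                 confusion_balanced_accuracy(y_true, y_pred))
  }

  # a uniform random guesser on the simulated 7-class windows lands near
  # chance level
  wd <- get_wd()
  set.seed(14)
  guess <- sample(levels(wd$labels), n_windows(wd), replace = TRUE)
  acc <- balanced_accuracy(wd$labels, guess)
  expect_gt(acc, 0.07)
  expect_lt(acc, 0.25)
})

test_that("the confidence interval scales with fold variance", {
  x <- c(0.8, 0.9, 0.85, 0.95, 0.75)
  halved <- mean(x) + (x - mean(x)) / 2  # quarter the variance
  expect_equal(ci95_halfwidth(halved), ci95_halfwidth(x) / 2)
  expect_equal(ci95_halfwidth(0.9), 0)
  expect_equal(ci95_halfwidth(x), qt(0.975, 4) * sd(x) / sqrt(5))
})

test_that("fold assignment is even, seeded and grouped by subject", {
  subs <- sprintf("P%02d", 1:12)
  f1 <- make_folds(subs, 5, 7)
  f2 <- make_folds(subs, 5, 7)
  expect_identical(f1, f2)
  expect_setequal(names(f1), subs)
  expect_equal(sort(as.vector(table(f1)), decreasing = TRUE),
               c(3L, 3L, 2L, 2L, 2L))
  expect_false(identical(make_folds(subs, 5, 8), f1))
  expect_error(make_folds(subs[1:4], 5, 1), "at least k")
})

test_that("cross-validation reports carry condition metadata and fold scores", {
  rpt <- crossval(get_tiny_manifest(), tiny_pipeline(), svm_config(),
                  k = 5, seed = 2)
  expect_s3_class(rpt, "cv_report")
  expect_length(rpt$per_fold, 5)
  expect_true(all(rpt$per_fold >= 0 & rpt$per_fold <= 1))
  expect_identical(rpt$condition$keypoint_set, "major_12")
  expect_identical(rpt$condition$model, "svm_config")
  expect_equal(rpt$mean, mean(rpt$per_fold))
})

test_that("keypoint subsets that drop the lower body lose the leg-driven classes", {
  reports <- run_keypoint_experiment(
    get_manifest(), c("major_12", "upper_8"),
    demo_pipeline("translate"), svm_config(), k = 5, seed = 1)
  expect_length(reports, 2)
  expect_identical(reports$upper_8$condition$keypoint_set, "upper_8")
  # pelvic tilt vs lumbar rotation differ only below the hips
  expect_lt(reports$upper_8$mean, reports$major_12$mean - 0.02)
})

test_that("grid search enumerates every combination and returns the argmax", {
  grid <- list(keypoint_sets = c("major_12", "upper_8"),
               transforms = c("none", "translate"))
  gs <- grid_search(get_tiny_manifest(), grid, tiny_pipeline(),
                    svm_config(), k = 5, seed = 2)
  expect_equal(nrow(gs$results), 4)
  expect_equal(nrow(gs$best), 1)
  expect_true(all(gs$best$mean >= gs$results$mean))
  # ties break towards the earliest enumerated row
  expect_equal(which(gs$results$mean == gs$best$mean)[1],
               as.integer(rownames(gs$best)))
})
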