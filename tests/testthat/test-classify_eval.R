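test_that("all four classifier kinds learn a separable problem and are seeded", {
  fm <- separable_features(n_per_class = 20)
  set.seed(3)
  idx <- sample(60, 45)
  xt <- fm$x[idx, ]; yt <- fm$labels[idx]; xe <- fm$x[-idx, ]

  for (kind in c("rf", "svm", "ann", "xgboost")) {
    pred <- train_and_predict(model_spec(kind), xt, yt, xe)
    expect_length(pred, nrow(xe))
    # training-set accuracy is at least chance for every kind
    self <- train_and_predict(model_spec(kind), xt, yt, xt)
    expect_gte(mean(self == yt), 1 / 3)
  }
  # the separable problem is solved exactly by the forest
  pred_rf <- train_and_predict(model_spec("rf"), xt, yt, xe)
  expect_equal(mean(pred_rf == fm$labels[-idx]), 1.0)

  for (kind in c("rf", "ann", "xgboost")) {
    p1 <- train_and_predict(model_spec(kind), xt, yt, xe)
    p2 <- train_and_predict(model_spec(kind), xt, yt, xe)
    expect_identical(p1, p2)
  }

  expect_error(train_and_predict(model_spec("rf"), xt, rep("a", 45), xe),
               "single class")
  expect_error(model_spec("rf", bogus = 1), "unknown parameter")
})

test_that("confusion matrices count truth rows against prediction columns", {
  lev <- c("a", "b", "c")
  y <- c("a", "a", "b", "c")
  cm <- confusion_matrix(y, y, levels = lev)
  expect_equal(diag(cm), c(a = 2, b = 1, c = 1))
  expect_equal(sum(cm), 4)

  one <- confusion_matrix("a", "c", levels = lev)
  expect_equal(one["a", "c"], 1)
  expect_equal(sum(one), 1)

  expect_error(confusion_matrix("a", "z", levels = lev), "outside")
  expect_error(confusion_matrix(c("a", "b"), "a"), "mismatch")
})

test_that("metrics match the printed formulas, including the accuracy-based F1", {
  # binary one-vs-rest counts TP=90 FN=10 TN=80 FP=20 embedded as class 1
  cm <- matrix(c(90, 20, 10, 80), 2, 2,
               dimnames = list(truth = c("pos", "neg"),
                               predicted = c("pos", "neg")))
  per <- metrics_from_confusion(cm, "per_class")
  expect_equal(per["pos", "SE"], 90)
  expect_equal(per["pos", "SP"], 80)
  expect_equal(per["pos", "AC"], 85)
  expect_equal(per["pos", "F1_paper"], 2 * 85 * 90 / (85 + 90))
  expect_equal(per["pos", "F1_paper"], 87.42857, tolerance = 1e-5)

  # the accuracy/sensitivity F1 is NOT the precision/recall F1 here
  prec <- 90 / (90 + 20) * 100
  expect_equal(per["pos", "F1_conventional"], 2 * prec * 90 / (prec + 90))
  expect_false(isTRUE(all.equal(per["pos", "F1_paper"],
                                per["pos", "F1_conventional"])))

  # binary symmetry: SE of one class equals SP of the other
  expect_equal(per["pos", "SE"], per["neg", "SP"])
  expect_equal(per["neg", "SE"], per["pos", "SP"])

  perfect <- diag(c(5, 7, 9))
  dimnames(perfect) <- list(truth = letters[1:3], predicted = letters[1:3])
  expect_equal(unname(metrics_from_confusion(perfect, "macro")[c("SE", "SP", "AC",
                                                                 "F1_paper")]),
               rep(100, 4))

  # degenerate class (never predicted, never true) -> NA excluded from macro
  deg <- matrix(c(5, 0, 0, 0), 2, 2,
                dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  expect_warning(m <- metrics_from_confusion(deg, "macro"), "undefined")
  expect_true(is.finite(m["AC"]))
})

test_that("t-based confidence intervals behave as the closed form dictates", {
  expect_equal(unname(confidence_interval(rep(0.8, 5))), c(80, 80))

  ci <- confidence_interval(c(0.9, 1.0))
  half <- qt(0.975, df = 1) * sd(c(90, 100)) / sqrt(2)
  expect_equal(unname(ci["low"]), max(0, 95 - half))
  expect_equal(unname(ci["high"]), 100)  # clipped

  s <- c(0.8, 0.85, 0.9, 0.95)
  w95 <- diff(confidence_interval(s, 0.95))
  w99 <- diff(confidence_interval(s, 0.99))
  expect_gte(w99, w95)
  expect_error(confidence_interval(0.9), "at least 2")
})

test_that("stratified k-fold pools the confusion and conserves sample counts", {
  fm <- separable_features(n_per_class = 20)
  rep10 <- kfold_cv(fm, spec = model_spec("rf"), k = 10, seed = 4)
  expect_equal(sum(rep10$confusion), 60)       # every sample evaluated once
  expect_equal(rep10$accuracy, 100)
  expect_length(rep10$fold_scores, 10)
  expect_identical(rep10$confusion,
                   kfold_cv(fm, spec = model_spec("rf"), k = 10, seed = 4)$confusion)

  # leave-one-out on 12 samples: 12 fold scores, each 0 or 1
  fm12 <- feature_matrix(fm$x[c(1:6, 21:26), ], fm$labels[c(1:6, 21:26)])
  loo <- kfold_cv(fm12, spec = model_spec("rf"), k = 6, seed = 1)
  expect_length(loo$fold_scores, 6)

  expect_error(kfold_cv(fm12, spec = model_spec("rf"), k = 10, seed = 1),
               "fewer samples")

  path <- tempfile(fileext = ".json")
  write_eval_report(rep10, path)
  blob <- jsonlite::read_json(path)
  expect_equal(blob$accuracy, 100)
  expect_true(file.exists(sub("\\.json$", "_confusion.csv", path)))
})
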