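test_that("all three base learners separate a wide-margin training set", {
  tab <- make_separable_table(n_per_class = 12, gap = 8, sd = 0.5)
  model <- train_ecm(tab)
  pred <- predict(model, tab)
  expect_equal(as.character(pred), as.character(tab$labels))
  base <- attr(pred, "base_predictions")
  for (nm in c("nb", "knn", "svm")) {
    expect_equal(as.character(base[[nm]]), as.character(tab$labels))
  }
  # determinism
  pred2 <- predict(model, tab)
  expect_equal(as.character(pred), as.character(pred2))
})

test_that("training preconditions are enforced", {
  tab <- make_separable_table(n_per_class = 3)
  expect_error(train_ecm(tab, knn_k = 6), "exceed")
  one <- labeled_table(matrix(rnorm(10), 5, 2), rep("b", 5))
  expect_error(train_ecm(one), "two classes")
})

test_that("the ensemble vote is the mode of the base predictions", {
  tab <- make_separable_table(n_per_class = 30, gap = 1.5, sd = 1, seed = 3)
  model <- train_ecm(tab)
  fresh <- make_separable_table(n_per_class = 50, gap = 1.5, sd = 1, seed = 4)
  pred <- predict(model, fresh)
  base <- attr(pred, "base_predictions")
  mode_oracle <- apply(base, 1, function(v)
    names(sort(table(v), decreasing = TRUE))[1])
  # 3 voters over 2 classes: the mode is unique and must match
  expect_equal(as.character(pred), unname(mode_oracle))
  # unanimity is always respected
  unanimous <- base$nb == base$knn & base$knn == base$svm
  expect_equal(as.character(pred)[unanimous],
               as.character(base$nb)[unanimous])
})

test_that("prediction rejects mismatched feature counts", {
  model <- train_ecm(make_separable_table())
  expect_error(predict(model, matrix(1, 2, 5)), "mismatch")
})

test_that("confusion counts match a hand tally", {
  y <- c(rep("malignant", 3), rep("benign", 2))
  cm <- confusion_matrix(y, y)
  expect_equal(cm[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  inv <- confusion_matrix(y, ifelse(y == "benign", "malignant", "benign"))
  expect_equal(inv$TP, 0L)
  expect_equal(inv$TN, 0L)
  expect_equal(inv$FP, 2L)
  expect_equal(inv$FN, 3L)

  withr::with_seed(8, {
    yt <- sample(c("benign", "malignant"), 20, TRUE)
    yp <- sample(c("benign", "malignant"), 20, TRUE)
  })
  cm2 <- confusion_matrix(yt, yp)
  tally <- table(truth = yt, pred = yp)
  expect_equal(cm2$TP, unname(tally["malignant", "malignant"]))
  expect_equal(cm2$TN, unname(tally["benign", "benign"]))
  expect_equal(cm2$FP, unname(tally["benign", "malignant"]))
  expect_equal(cm2$FN, unname(tally["malignant", "benign"]))
  expect_equal(cm2$TP + cm2$TN + cm2$FP + cm2$FN, 20L)

  expect_error(confusion_matrix(yt, yp[-1]), "equal length")
})

test_that("metric formulas and edge cases behave as defined", {
  cm <- confusion_matrix(c("malignant", "benign"), c("malignant", "benign"))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$error, 0)
  expect_equal(m$f1, 1)

  # zero positive predictions: precision defined as 0, then F1 = 0
  cm0 <- confusion_matrix(c("malignant", "benign"),
                          c("benign", "benign"))
  expect_warning(m0 <- classification_metrics(cm0), "zero denominator")
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)

  # harmonic-mean bound and accuracy + error = 1 across random matrices
  withr::with_seed(12, {
    for (i in 1:20) {
      counts <- rmultinom(1, 40, rep(0.25, 4))
      cm <- structure(list(TP = counts[1], TN = counts[2], FP = counts[3],
                           FN = counts[4], positive = "malignant"),
                      class = "confusion_matrix")
      m <- suppressWarnings(classification_metrics(cm))
      expect_equal(m$accuracy + m$error, 1)
      if (m$precision + m$recall > 0) {
        expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
        expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      }
    }
  })
})

test_that("percentage rendering truncates rather than rounds", {
  expect_equal(pct_truncate(94.29995), 94.299)
  expect_equal(pct_truncate(98.1995926), 98.199)
  m <- structure(list(accuracy = 0.94299951), class = "metrics_report")
  expect_equal(unname(metrics_percent(m)["accuracy"]), 94.299)
})

test_that("stratified folds partition the data evenly within classes", {
  labels <- factor(rep(c("b", "m"), c(33, 17)))
  fold <- stratified_folds(labels, 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  sizes <- tabulate(fold, 5)
  expect_lte(diff(range(sizes)), 1)
  for (cl in levels(labels)) {
    per <- tabulate(fold[labels == cl], 5)
    expect_lte(diff(range(per)), 1)
  }
  expect_error(stratified_folds(factor(rep(c("b", "m"), c(30, 3))), 5),
               "at least 5")
})

test_that("cross-validation runs the full pipeline fold-safely", {
  sim <- generate_synthetic(synthetic_spec(n_per_class = 25, b = 4,
                                           outlier_rate = 0.04, seed = 6))
  cfg <- fast_config(cv_folds = 5, seed = 31)
  cv <- suppressWarnings(cross_validate(sim$table, cfg))
  expect_length(cv$folds, 5)
  # test folds partition all instances
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(length(cv$fold_assignment), 50)
  sizes <- vapply(cv$folds, function(f) f$n_test, numeric(1))
  expect_equal(sum(sizes), 50)
  expect_lte(diff(range(sizes)), 1)
  # mean metrics are the arithmetic mean of the per-fold metrics
  for (nm in c("accuracy", "precision", "recall", "error", "f1")) {
    per_fold <- vapply(cv$folds, function(f) f$metrics[[nm]], numeric(1))
    expect_equal(cv$mean_metrics[[nm]], mean(per_fold))
  }
  expect_equal(cv$mean_metrics$accuracy + cv$mean_metrics$error, 1)
})
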