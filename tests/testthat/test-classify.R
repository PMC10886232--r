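test_that("confusion matrices count true-by-predicted with fixed class order", {
  cls <- c("non", "mi", "ms")
  perfect <- confusion_matrix(cls, cls, cls)
  expect_equal(diag(perfect), c(non = 1, mi = 1, ms = 1))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  all_one <- confusion_matrix(c("non", "mi", "ms"), rep("mi", 3), cls)
  expect_equal(colSums(all_one), c(non = 0, mi = 3, ms = 0))

  expect_error(confusion_matrix("non", "severe", cls), "severe")
  expect_error(confusion_matrix(c("non", "mi"), "non", cls), "length")

  set.seed(10)
  tr <- sample(cls, 50, replace = TRUE)
  pr <- sample(cls, 50, replace = TRUE)
  cm <- confusion_matrix(tr, pr, cls)
  expect_equal(rowSums(cm), vapply(cls, function(c) sum(tr == c), numeric(1)))
  expect_equal(sum(cm), 50)
})

test_that("the worked 298-of-317 example yields 94.0% accuracy", {
  cm <- matrix(c(160, 7, 12, 138), 2, 2, byrow = TRUE,
    dimnames = list(c("control", "patient"), c("control", "patient"))
  )
  expect_equal(sum(diag(cm)), 298)
  expect_equal(sum(cm), 317)
  rep <- eval_metrics(cm)
  expect_equal(round(100 * rep$accuracy, 1), 94.0)
})

test_that("weighted recall equals accuracy and all metrics lie in [0, 1]", {
  expect_equal(eval_metrics(diag(c(5, 7, 9)))$accuracy, 1)
  expect_equal(eval_metrics(diag(c(5, 7, 9)))$weighted_f1, 1)
  set.seed(19)
  for (i in 1:25) {
    cm <- matrix(rpois(9, 4), 3, 3)
    if (sum(cm) == 0) next
    r <- eval_metrics(cm)
    expect_equal(r$weighted_recall, r$accuracy, tolerance = 1e-12)
    expect_true(all(unlist(r[c(
      "accuracy", "weighted_precision",
      "weighted_recall", "weighted_f1"
    )]) >= 0))
    expect_true(all(unlist(r[c(
      "accuracy", "weighted_precision",
      "weighted_recall", "weighted_f1"
    )]) <= 1))
  }
  expect_error(eval_metrics(matrix(0, 2, 2)), "positive")
  # never-predicted class flagged with precision 0
  cm <- matrix(c(3, 2, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  r <- eval_metrics(cm)
  expect_equal(r$zero_prediction_classes, "b")
  expect_equal(r$per_class$precision[2], 0)
})

test_that("k-fold splits partition the indices with near-equal, stratified folds", {
  folds <- kfold_split(10, k = 5, rng_seed = 3)
  expect_length(folds, 5)
  expect_equal(vapply(folds, length, 1L), rep(2L, 5))
  expect_equal(sort(unlist(folds)), 1:10)

  labs <- rep(c("a", "b", "c"), each = 10)
  sf <- kfold_split(30, k = 5, rng_seed = 3, stratify_labels = labs)
  expect_equal(sort(unlist(sf)), 1:30)
  for (f in sf) expect_equal(as.integer(table(labs[f])), c(2L, 2L, 2L))

  # sizes differ by at most one without stratification
  f11 <- kfold_split(11, k = 3, rng_seed = 1)
  expect_lte(diff(range(vapply(f11, length, 1L))), 1)
  expect_error(kfold_split(3, k = 5), "exceeds")
})

test_that("fit_predict is deterministic, honours degenerate training sets, and validates names", {
  co <- small_sensory_cohort(seed = 41, counts = c(non = 6, mi = 6, ms = 6))
  f <- featurize_cohort(co)
  p1 <- fit_predict(f, f, "rf", seed = 7)
  for (i in 1:4) expect_identical(fit_predict(f, f, "rf", seed = 7), p1)

  single <- f[f$label == "mi", ]
  expect_true(all(fit_predict(single, f, "rf", seed = 1) == "mi"))

  f_bad <- f
  names(f_bad)[4] <- "renamed_feature"
  expect_error(fit_predict(f, f_bad, "rf"), "renamed_feature")
  expect_error(fit_predict(f, f, "svm"), "rf, gb, mlp, lr, knn")
})

test_that("cross-validation returns k fold reports and a sane pooled report", {
  co <- small_sensory_cohort(seed = 55, counts = c(non = 8, mi = 8, ms = 8))
  f <- featurize_cohort(co)
  cv <- cross_validate(f, "knn", k = 4, seed = 5)
  expect_length(cv$fold_reports, 4)
  expect_equal(sum(cv$pooled$confusion), nrow(f))
  expect_gte(cv$mean_accuracy, 0)
  expect_equal(
    cv$mean_accuracy,
    mean(vapply(cv$fold_reports, function(r) r$accuracy, numeric(1)))
  )
  expect_equal(nrow(tidy(cv)), 4)
  expect_equal(glance(cv)$model, "knn")
  expect_error(cross_validate(f, "boost"), "Valid")
})

test_that("grid search never sees held-out fold labels", {
  co <- small_sensory_cohort(seed = 66, counts = c(non = 8, mi = 8, ms = 8))
  f <- featurize_cohort(co)
  folds <- kfold_split(nrow(f), k = 4, rng_seed = 9, stratify_labels = f$label)
  cv1 <- cross_validate(f, "knn", seed = 9, folds = folds)
  # corrupt the labels of fold 1's test rows only: chosen hyperparameters
  # for that fold must not change (tuning only used the training portion)
  set.seed(123)
  f2 <- f
  f2$label[folds[[1]]] <- sample(c("non", "mi", "ms"), length(folds[[1]]), replace = TRUE)
  cv2 <- cross_validate(f2, "knn", seed = 9, folds = folds)
  expect_identical(cv1$fold_params[[1]], cv2$fold_params[[1]])
})
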