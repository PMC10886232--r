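#' Confusion matrix with fixed class order
#'
#' @param true_labels,pred_labels Equal-length label vectors, values drawn
#'   from `class_order`.
#' @param class_order Character vector fixing row/column order (rows = true
#'   class, columns = predicted class).
#' @return A square integer count matrix.
#' @export
confusion_matrix <- function(true_labels, pred_labels, class_order) {
  if (length(true_labels) != length(pred_labels)) {
    stop("Label vectors differ in length.", call. = FALSE)
  }
  unknown <- setdiff(unique(c(true_labels, pred_labels)), class_order)
  if (length(unknown) > 0L) {
    stop("Label(s) not in class_order: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  t_f <- factor(true_labels, levels = class_order)
  p_f <- factor(pred_labels, levels = class_order)
  m <- table(true = t_f, predicted = p_f)
  matrix(as.integer(m), nrow = length(class_order), dimnames = dimnames(m))
}

#' Evaluation metrics from a confusion matrix
#'
#' Computes accuracy (trace over total) and the support-weighted average
#' precision, recall and F1: per class `i` with support `|y_i|`, one-vs-rest
#' TP/FP/FN give precision and recall, and the weighted aggregate is
#' `sum(|y_i| * m_i) / sum(|y_i|)`. For single-label classification the
#' weighted recall is algebraically identical to accuracy. A class that is
#' never predicted gets precision 0 and is flagged.
#'
#' @param confusion Square non-negative count matrix (rows true, columns
#'   predicted), total > 0.
#' @return An `eval_report`: list with `confusion`, `accuracy`,
#'   `weighted_precision`, `weighted_recall`, `weighted_f1` (all fractions
#'   in `[0, 1]`), `per_class` tibble and `zero_prediction_classes`.
#' @export
eval_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("Confusion matrix must be square.", call. = FALSE)
  if (any(confusion < 0)) stop("Confusion matrix must be non-negative.", call. = FALSE)
  total <- sum(confusion)
  if (total <= 0) stop("Confusion matrix total must be positive.", call. = FALSE)
  classes <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  if (is.null(dimnames(confusion))) dimnames(confusion) <- list(classes, classes)
  tp <- unname(diag(confusion))
  support <- unname(rowSums(confusion))
  predicted <- unname(colSums(confusion))
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  w <- support / total
  per_class <- tibble::tibble(
    class = classes, support = as.integer(support),
    precision = precision, recall = recall, f1 = f1
  )
  structure(
    list(
      confusion = confusion,
      accuracy = sum(tp) / total,
      weighted_precision = sum(w * precision),
      weighted_recall = sum(w * recall),
      weighted_f1 = sum(w * f1),
      per_class = per_class,
      zero_prediction_classes = classes[predicted == 0 & support > 0]
    ),
    class = "eval_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", sum(x$confusion), "\n")
  print(x$confusion)
  cat(sprintf(
    "accuracy %.1f%%  weighted P %.1f%%  R %.1f%%  F1 %.1f%%\n",
    100 * x$accuracy, 100 * x$weighted_precision,
    100 * x$weighted_recall, 100 * x$weighted_f1
  ))
  if (length(x$zero_prediction_classes) > 0L) {
    cat("never predicted:", paste(x$zero_prediction_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname eval_metrics
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @rdname eval_metrics
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    n = sum(x$confusion), accuracy = x$accuracy,
    weighted_precision = x$weighted_precision,
    weighted_recall = x$weighted_recall, weighted_f1 = x$weighted_f1
  )
}

#' Seeded (optionally stratified) k-fold split
#'
#' Partitions `0 < n` sample indices into `k` disjoint test folds whose
#' sizes differ by at most one; with `stratify_labels` the per-class counts
#' are balanced the same way across folds.
#'
#' @param n_samples Number of samples.
#' @param k Number of folds (default 5).
#' @param rng_seed Integer seed for the shuffle.
#' @param stratify_labels Optional label vector of length `n_samples`.
#' @return List of `k` integer index vectors (1-based), pairwise disjoint,
#'   union `1:n_samples`.
#' @export
kfold_split <- function(n_samples, k = 5, rng_seed = 1L, stratify_labels = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2.", call. = FALSE)
  if (k > n_samples) stop("`k` (", k, ") exceeds the number of samples (", n_samples, ").", call. = FALSE)
  set.seed(rng_seed)
  folds <- vector("list", k)
  assign_group <- function(idx) {
    idx <- sample(idx)
    fold_of <- rep(seq_len(k), length.out = length(idx))
    split(idx, fold_of)
  }
  if (is.null(stratify_labels)) {
    parts <- assign_group(seq_len(n_samples))
    folds <- lapply(seq_len(k), function(f) sort(parts[[as.character(f)]] %||% integer(0)))
  } else {
    stopifnot(length(stratify_labels) == n_samples)
    acc <- rep(list(integer(0)), k)
    for (cl in unique(stratify_labels)) {
      parts <- assign_group(which(stratify_labels == cl))
      for (f in names(parts)) {
        fi <- as.integer(f)
        acc[[fi]] <- c(acc[[fi]], parts[[f]])
      }
    }
    folds <- lapply(acc, sort)
  }
  folds
}

# ---- model bank -----------------------------------------------------------

cls_model_names <- c("rf", "gb", "mlp", "lr", "knn")

#' Default hyperparameter grids of the classifier bank
#'
#' Small documented grids searched exhaustively by [cross_validate()]'s
#' inner loop: random forest (`rf`) trees and mtry; gradient boosting
#' (`gb`) rounds and depth; multilayer perceptron (`mlp`) hidden width and
#' weight decay (fitted for up to 100 optimisation epochs); logistic
#' regression (`lr`, multinomial with weight decay) regularisation
#' strength; K-nearest neighbours (`knn`) K in 3/5/7.
#'
#' @param model_name One of `"rf"`, `"gb"`, `"mlp"`, `"lr"`, `"knn"`.
#' @return A data frame, one row per grid point.
#' @export
default_grid <- function(model_name) {
  switch(model_name,
    rf = expand.grid(ntree = c(100, 300), mtry_frac = c(0.1, 0.33)),
    gb = expand.grid(nrounds = c(50, 100), max_depth = c(3, 6)),
    mlp = expand.grid(size = c(8, 16), decay = c(0.001, 0.01)),
    lr = expand.grid(decay = c(0.1, 1, 10)),
    knn = expand.grid(k = c(3, 5, 7)),
    stop("Unknown model '", model_name, "'. Valid: ", paste(cls_model_names, collapse = ", "), call. = FALSE)
  )
}

feature_xy <- function(features, class_order = NULL) {
  meta <- intersect(c("subject_id", "hand", "label"), names(features))
  x <- as.matrix(features[setdiff(names(features), meta)])
  y <- if ("label" %in% meta) features$label else NULL
  if (!is.null(y) && is.null(class_order)) class_order <- unique(y)
  list(x = x, y = if (is.null(y)) NULL else factor(y, levels = class_order), classes = class_order)
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
standardize_apply <- function(x, s) sweep(sweep(x, 2, s$mu), 2, s$sd, "/")

fit_bank_model <- function(x, y, model_name, params, seed = 1L) {
  set.seed(seed)
  if (length(unique(as.character(y))) == 1L) {
    # degenerate training set: predict the single observed class
    return(structure(
      list(
        fit = as.character(y[1]), model_name = "constant", params = params,
        scaler = NULL, classes = levels(y)
      ),
      class = "bank_model"
    ))
  }
  scaler <- NULL
  if (model_name %in% c("mlp", "lr", "knn")) {
    scaler <- standardize_fit(x)
    x <- standardize_apply(x, scaler)
  }
  fit <- switch(model_name,
    rf = randomForest::randomForest(
      x = x, y = y, ntree = params$ntree,
      mtry = max(1L, floor(params$mtry_frac * ncol(x)))
    ),
    gb = xgboost::xgboost(
      x, y,
      nrounds = params$nrounds, max_depth = params$max_depth,
      learning_rate = 0.3, nthreads = 1, verbosity = 0, seed = seed
    ),
    mlp = nnet::nnet(
      x = x, y = nnet::class.ind(y), size = params$size, decay = params$decay,
      maxit = 100, softmax = TRUE, trace = FALSE, MaxNWts = 100000
    ),
    lr = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df,
        decay = params$decay, maxit = 200, trace = FALSE, MaxNWts = 100000
      )
    },
    knn = list(x = x, y = y, k = params$k), # lazy learner: store the data
    stop("Unknown model '", model_name, "'. Valid: ", paste(cls_model_names, collapse = ", "), call. = FALSE)
  )
  structure(
    list(fit = fit, model_name = model_name, params = params, scaler = scaler, classes = levels(y)),
    class = "bank_model"
  )
}

predict_bank_model <- function(model, x_new) {
  if (model$model_name == "constant") return(rep(model$fit, nrow(x_new)))
  if (!is.null(model$scaler)) x_new <- standardize_apply(x_new, model$scaler)
  out <- switch(model$model_name,
    rf = as.character(stats::predict(model$fit, x_new)),
    gb = as.character(stats::predict(model$fit, x_new, type = "class")),
    mlp = {
      pm <- stats::predict(model$fit, x_new)
      model$classes[max.col(pm, ties.method = "first")]
    },
    lr = as.character(stats::predict(model$fit, data.frame(x_new, check.names = FALSE))),
    knn = as.character(class::knn(model$fit$x, x_new, model$fit$y,
      k = min(model$fit$k, nrow(model$fit$x))
    ))
  )
  out
}

#' Train on one feature table, predict on another
#'
#' @param features_train,features_test Feature tibbles with matching feature
#'   columns (see [featurize_cohort()]); `features_test` may omit `label`.
#' @param model_name One of `"rf"`, `"gb"`, `"mlp"`, `"lr"`, `"knn"`.
#' @param params One-row data frame / list of hyperparameters (defaults:
#'   first row of [default_grid()]).
#' @param class_order Label order (default: the sensory or motor class set
#'   inferred from the training labels).
#' @param seed RNG seed making the fit deterministic.
#' @return Character vector of predicted labels, one per test row.
#' @export
fit_predict <- function(features_train, features_test, model_name,
                        params = NULL, class_order = NULL, seed = 1L) {
  meta <- c("subject_id", "hand", "label")
  tr_feats <- setdiff(names(features_train), meta)
  te_feats <- setdiff(names(features_test), meta)
  di <- union(setdiff(tr_feats, te_feats), setdiff(te_feats, tr_feats))
  if (length(di) > 0L) {
    stop("Train/test feature name mismatch: ", paste(di, collapse = ", "), call. = FALSE)
  }
  if (is.null(class_order)) {
    class_order <- infer_class_order(features_train$label)
  }
  if (is.null(params)) params <- default_grid(model_name)[1, , drop = FALSE]
  xy <- feature_xy(features_train, class_order)
  model <- fit_bank_model(xy$x, xy$y, model_name, params, seed = seed)
  x_new <- as.matrix(features_test[tr_feats])
  predict_bank_model(model, x_new)
}

infer_class_order <- function(labels) {
  for (m in c("sensory", "motor")) {
    if (all(labels %in% ncs_class_order(m))) return(ncs_class_order(m))
  }
  sort(unique(labels))
}

#' Grid-searched k-fold cross-validation of the classifier bank
#'
#' The evaluation protocol: the hands are split into `k` stratified folds;
#' per fold, an exhaustive grid search (inner `inner_k`-fold CV on the
#' training portion only — the held-out fold is never seen by tuning)
#' selects the hyperparameters, the best configuration is refit on the full
#' training portion and evaluated on the held-out fold. Reported accuracy is
#' the unweighted mean of the fold accuracies.
#'
#' @param features A feature tibble with `label`.
#' @param model_name One of `"rf"`, `"gb"`, `"mlp"`, `"lr"`, `"knn"`.
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param k Number of outer folds (default 5).
#' @param seed RNG seed driving the splits and fits.
#' @param inner_k Inner folds for grid search (default 3).
#' @param class_order Fixed label order for confusion matrices.
#' @param folds Optional list of test-index vectors overriding the
#'   stratified split (length sets `k`).
#' @return A `cv_result`: list with `mean_accuracy`, `fold_reports` (list of
#'   [eval_metrics()] reports), `fold_params`, `pooled` report over all
#'   held-out predictions, `model_name`, `k`.
#' @export
cross_validate <- function(features, model_name, grid = NULL, k = 5, seed = 1L,
                           inner_k = 3, class_order = NULL, folds = NULL) {
  if (!model_name %in% cls_model_names) {
    stop("Unknown model '", model_name, "'. Valid: ", paste(cls_model_names, collapse = ", "), call. = FALSE)
  }
  if (is.null(grid)) grid <- default_grid(model_name)
  if (is.null(class_order)) class_order <- infer_class_order(features$label)
  if (length(unique(features$label)) < 2L) stop("Labels are degenerate (single class).", call. = FALSE)
  n <- nrow(features)
  if (is.null(folds)) {
    folds <- kfold_split(n, k = k, rng_seed = seed, stratify_labels = features$label)
  } else {
    k <- length(folds)
  }
  fold_reports <- vector("list", k)
  fold_params <- vector("list", k)
  truth_all <- character(0)
  pred_all <- character(0)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train <- features[-test_idx, , drop = FALSE]
    test <- features[test_idx, , drop = FALSE]
    # inner grid search on the training portion only
    best <- NULL
    best_acc <- -Inf
    inner <- kfold_split(nrow(train),
      k = min(inner_k, max(2L, min(table(train$label)))),
      rng_seed = seed + f, stratify_labels = train$label
    )
    for (g in seq_len(nrow(grid))) {
      params <- grid[g, , drop = FALSE]
      accs <- vapply(inner, function(iidx) {
        pred <- fit_predict(
          train[-iidx, , drop = FALSE], train[iidx, , drop = FALSE],
          model_name, params,
          class_order = class_order, seed = seed + f
        )
        mean(pred == train$label[iidx])
      }, numeric(1))
      if (mean(accs) > best_acc) {
        best_acc <- mean(accs)
        best <- params
      }
    }
    pred <- fit_predict(train, test, model_name, best, class_order = class_order, seed = seed + f)
    fold_reports[[f]] <- eval_metrics(confusion_matrix(test$label, pred, class_order))
    fold_params[[f]] <- best
    truth_all <- c(truth_all, test$label)
    pred_all <- c(pred_all, pred)
  }
  structure(
    list(
      mean_accuracy = mean(vapply(fold_reports, function(r) r$accuracy, numeric(1))),
      fold_reports = fold_reports, fold_params = fold_params,
      pooled = eval_metrics(confusion_matrix(truth_all, pred_all, class_order)),
      model_name = model_name, k = k, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(
    "<cv_result>", x$model_name, "-", x$k, "folds; mean accuracy",
    sprintf("%.1f%%", 100 * x$mean_accuracy), "\n"
  )
  print(x$pooled$confusion)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @param ... Unused.
#' @export
tidy.cv_result <- function(x, ...) {
  purrr::imap_dfr(x$fold_reports, function(r, f) {
    dplyr::mutate(glance(r), fold = f, .before = 1)
  })
}

#' @rdname cross_validate
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, k = x$k, mean_accuracy = x$mean_accuracy,
    pooled_accuracy = x$pooled$accuracy,
    pooled_weighted_f1 = x$pooled$weighted_f1
  )
}
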