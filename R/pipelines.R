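write_run_manifest <- function(out_dir, manifest) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

pkg_version <- function() as.character(utils::packageVersion("ncsdx"))

#' End-to-end motor (CMAP) pipeline
#'
#' Runs the full motor chain on a signal table: optional Gaussian-noise
#' duplication augmentation, STFT spectrogram images with one shared dB
#' scale, CNN training on a stratified training split, and evaluation on
#' the held-out split. All intermediates (signal table, images, history,
#' report, run manifest) are written under `out_dir`.
#'
#' @param signals A motor signal tibble, or a CSV path readable by
#'   [read_signal_table()].
#' @param out_dir Output directory.
#' @param cfg A [conv_net_config()].
#' @param augment Apply [augment_gaussian()] to the training split
#'   (default TRUE).
#' @param noise_scale Augmentation noise scale (default 0.8).
#' @param holdout_frac Stratified fraction held out for evaluation
#'   (default 0.25).
#' @param seed Seed driving the split and augmentation; the CNN uses
#'   `cfg$rng_seed`.
#' @return A list with `model` (`cnn_model`), `report` ([eval_metrics()] on
#'   the held-out split), `train_report`, and `paths`.
#' @export
pipeline_motor <- function(signals, out_dir, cfg = conv_net_config(),
                           augment = TRUE, noise_scale = 0.8,
                           holdout_frac = 0.25, seed = 1L) {
  records <- if (is.character(signals)) read_signal_table(signals, "motor") else signals
  validate_signal_table(records)
  if (nrow(records) == 0L) stop("Motor pipeline: empty input signal table.", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  classes <- ncs_class_order("motor")

  # stratified holdout split on original records
  set.seed(seed)
  test_idx <- unlist(lapply(classes, function(cl) {
    idx <- which(records$label == cl)
    sample(idx, size = max(1L, round(holdout_frac * length(idx))))
  }))
  train <- records[-test_idx, , drop = FALSE]
  test <- records[test_idx, , drop = FALSE]
  if (augment) train <- augment_gaussian(train, noise_scale = noise_scale, rng_seed = seed)
  write_signal_table(train, file.path(out_dir, "train_signals.csv"))

  img_train <- spectrogram_images(train, out_dir = file.path(out_dir, "images"))
  db <- c(img_train$image[[1]]$db_floor, img_train$image[[1]]$db_ceiling)
  img_test <- spectrogram_images(test)
  img_test$image <- purrr::map(test$trace, function(tr) {
    render_spectrogram_image(spectrogram(tr), db_floor = db[1], db_ceiling = db[2])
  })

  model <- train_cnn(img_train, cfg = cfg)
  pred_test <- predict_cnn(model, img_test)
  report <- eval_metrics(confusion_matrix(test$label, pred_test$label, classes))
  pred_train <- predict_cnn(model, img_train)
  train_report <- eval_metrics(confusion_matrix(img_train$label, pred_train$label, classes))

  readr::write_csv(model$history, file.path(out_dir, "train_history.csv"))
  jsonlite::write_json(
    list(
      confusion = report$confusion, accuracy = report$accuracy,
      weighted_precision = report$weighted_precision,
      weighted_recall = report$weighted_recall, weighted_f1 = report$weighted_f1
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_run_manifest(out_dir, list(
    pipeline = "motor", version = pkg_version(), seed = seed,
    cfg = cfg[setdiff(names(cfg), "blocks")], blocks = cfg$blocks,
    augment = augment, noise_scale = noise_scale, holdout_frac = holdout_frac,
    n_train = nrow(train), n_test = nrow(test),
    db_floor = db[1], db_ceiling = db[2]
  ))
  list(
    model = model, report = report, train_report = train_report,
    paths = list(out_dir = out_dir)
  )
}

#' End-to-end sensory (SNAP) pipeline
#'
#' Runs the full sensory chain: optional augmentation, Haar wavelet
#' 135-feature extraction per hand (hands missing a nerve are excluded with
#' a warning), and grid-searched k-fold cross-validation of the chosen
#' classifier. Intermediates (feature table, report, manifest) are written
#' under `out_dir`.
#'
#' @param signals A sensory signal tibble, or a CSV path.
#' @param out_dir Output directory.
#' @param model_name Classifier (default `"rf"`), see [cross_validate()].
#' @param augment Apply [augment_gaussian()] before feature extraction
#'   (default FALSE).
#' @param noise_scale Augmentation noise scale (default 0.8).
#' @param k CV folds (default 5).
#' @param seed Seed driving augmentation, splits and fits.
#' @param alpha,n_bins Renyi entropy configuration for the features.
#' @return A list with `cv` (`cv_result`), `report` (the pooled
#'   [eval_metrics()] report), `features` (the feature tibble) and `paths`.
#' @export
pipeline_sensory <- function(signals, out_dir, model_name = "rf",
                             augment = FALSE, noise_scale = 0.8, k = 5,
                             seed = 1L, alpha = 2, n_bins = 16) {
  records <- if (is.character(signals)) read_signal_table(signals, "sensory") else signals
  if (nrow(records) == 0L) stop("Sensory pipeline: empty input signal table.", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (augment) records <- augment_gaussian(records, noise_scale = noise_scale, rng_seed = seed)
  features <- featurize_cohort(records, alpha = alpha, n_bins = n_bins)
  write_feature_table(features, file.path(out_dir, "features.csv"))
  cv <- cross_validate(features, model_name,
    k = k, seed = seed,
    class_order = ncs_class_order("sensory")
  )
  jsonlite::write_json(
    list(
      model = model_name, mean_accuracy = cv$mean_accuracy,
      confusion = cv$pooled$confusion, accuracy = cv$pooled$accuracy,
      weighted_precision = cv$pooled$weighted_precision,
      weighted_recall = cv$pooled$weighted_recall,
      weighted_f1 = cv$pooled$weighted_f1,
      fold_params = cv$fold_params
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_run_manifest(out_dir, list(
    pipeline = "sensory", version = pkg_version(), seed = seed,
    model = model_name, k = k, augment = augment, noise_scale = noise_scale,
    renyi_alpha = alpha, renyi_bins = n_bins,
    n_hands = nrow(features)
  ))
  list(cv = cv, report = cv$pooled, features = features, paths = list(out_dir = out_dir))
}
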