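#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram as a time-frequency heat map
#' @param object An `ncs_spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ncs_spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    bin = seq_len(nrow(object$power)) - 1L,
    frame = seq_len(ncol(object$power)) - 1L
  )
  df$db <- as.vector(10 * log10(t(object$power)[cbind(df$frame + 1L, df$bin + 1L)] + 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$bin, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power (dB)") +
    ggplot2::labs(x = "frame", y = "frequency bin", title = object$source_id) +
    ggplot2::theme_minimal()
}

#' Plot a rendered spectrogram image
#' @param object A `spectrogram_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram_image <- function(object, ...) {
  px <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$intensity <- px[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = object$source_id) +
    ggplot2::theme_void()
}

#' Plot CNN training curves
#' @param object A `cnn_model` (or the tibble from [tune_learning_rate()]).
#' @param ... Unused.
#' @return A ggplot of loss and accuracy per epoch.
#' @export
autoplot.cnn_model <- function(object, ...) {
  plot_train_history(object$history)
}

#' Accuracy/loss curves for one or more training histories
#' @param history Tibble with `epoch`, `loss`, `accuracy` and optionally
#'   `learning_rate` (one curve per rate).
#' @return A ggplot, faceted metric by row.
#' @export
plot_train_history <- function(history) {
  long <- tidyr::pivot_longer(history, c("loss", "accuracy"),
    names_to = "metric", values_to = "value"
  )
  p <- if ("learning_rate" %in% names(history)) {
    ggplot2::ggplot(long, ggplot2::aes(
      x = .data$epoch, y = .data$value,
      colour = factor(.data$learning_rate)
    )) +
      ggplot2::labs(colour = "learning rate")
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report's confusion matrix
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot heat map, rows true class, columns predicted.
#' @export
autoplot.eval_report <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(
    true = factor(rownames(cm), levels = rev(rownames(cm))),
    predicted = factor(colnames(cm), levels = colnames(cm))
  )
  df$count <- as.vector(t(cm[rev(seq_len(nrow(cm))), , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true, fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("accuracy %.1f%%", 100 * object$accuracy),
      x = "predicted", y = "true"
    ) +
    ggplot2::theme_minimal()
}

#' Plot simulated NCS traces by class
#' @param records A signal tibble; one line per trace, faceted by nerve,
#'   coloured by label.
#' @param max_per_class Traces drawn per (label, nerve) (default 5).
#' @return A ggplot.
#' @export
plot_waveforms <- function(records, max_per_class = 5) {
  validate_signal_table(records)
  df <- records |>
    dplyr::group_by(.data$label, .data$nerve) |>
    dplyr::slice_head(n = max_per_class) |>
    dplyr::ungroup()
  long <- tidyr::unnest(
    dplyr::mutate(df,
      t_ms = purrr::map(.data$trace, ~ (seq_along(.x) - 1) / length(.x) * 6),
      id = paste0(.data$subject_id, "_", .data$hand, "_", .data$nerve)
    ),
    c("t_ms", "trace")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$t_ms, y = .data$trace,
    group = .data$id, colour = .data$label
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$nerve), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "amplitude") +
    ggplot2::theme_minimal()
}
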