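#' Configuration of the spectrogram CNN
#'
#' The fixed three-block architecture used for motor-trace classification:
#' per block a valid-mode 2-D convolution (`kernels` filters of
#' `kernel_size` x `kernel_size`), ReLU, and `pool_size` x `pool_size` max
#' pooling, followed by flatten, dropout, a 256-unit ReLU dense layer and a
#' single sigmoid output trained with binary cross-entropy. Defaults are the
#' tuned settings: blocks (16,4,3), (32,4,3), (64,4,2) on a 256 x 256 input,
#' learning rate 0.005, batch size 3, 30 epochs.
#'
#' @param input_side Input image side length in pixels.
#' @param blocks 3-column matrix (kernels, kernel_size, pool_size), one row
#'   per block.
#' @param dense_width Units in the penultimate dense layer.
#' @param dropout_rate Dropout probability on the flattened features,
#'   in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param optimizer `"adam"` (default) or plain `"sgd"`.
#' @param rng_seed Seed controlling weight initialisation, shuffling and
#'   dropout.
#' @return A `conv_net_config` list.
#' @export
conv_net_config <- function(input_side = 256,
                            blocks = rbind(c(16, 4, 3), c(32, 4, 3), c(64, 4, 2)),
                            dense_width = 256, dropout_rate = 0.5,
                            learning_rate = 0.005, batch_size = 3, epochs = 30,
                            optimizer = c("adam", "sgd"), rng_seed = 1L) {
  blocks <- matrix(as.integer(blocks), ncol = 3)
  colnames(blocks) <- c("kernels", "kernel_size", "pool_size")
  stopifnot(
    input_side >= 1, nrow(blocks) >= 1, all(blocks >= 1),
    dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
    batch_size >= 1, epochs >= 1
  )
  cfg <- list(
    input_side = as.integer(input_side), blocks = blocks,
    dense_width = as.integer(dense_width), dropout_rate = dropout_rate,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), optimizer = match.arg(optimizer),
    rng_seed = as.integer(rng_seed)
  )
  layer_shapes(structure(cfg, class = "conv_net_config")) # validates feasibility
  structure(cfg, class = "conv_net_config")
}

#' Feature-map shapes of the CNN stack
#'
#' Per block, a valid-mode convolution shrinks the side to
#' `side - kernel_size + 1` and pooling floor-divides it by `pool_size`.
#' At the defaults this gives 84 x 84 x 16, 27 x 27 x 32 and 12 x 12 x 64,
#' then flatten (9216), dense (256) and the single output unit.
#'
#' @param cfg A [conv_net_config()].
#' @return A tibble with `layer`, `side`, `channels`, `units`.
#' @export
layer_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "conv_net_config") || is.list(cfg))
  side <- cfg$input_side
  rows <- list(tibble::tibble(layer = "input", side = side, channels = 1L, units = side^2))
  for (b in seq_len(nrow(cfg$blocks))) {
    k <- unname(cfg$blocks[b, 2])
    p <- unname(cfg$blocks[b, 3])
    conv_side <- side - k + 1L
    if (conv_side < 1L) {
      stop("Block ", b, ": convolution collapses the ", side, "-pixel side below 1.", call. = FALSE)
    }
    side <- conv_side %/% p
    if (side < 1L) {
      stop("Block ", b, ": pooling collapses the ", conv_side, "-pixel side below 1.", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = paste0("block", b), side = side,
      channels = unname(cfg$blocks[b, 1]),
      units = side^2 * unname(cfg$blocks[b, 1])
    )
  }
  flat <- rows[[length(rows)]]$units
  rows[[length(rows) + 1L]] <- tibble::tibble(layer = "flatten", side = NA_integer_, channels = NA_integer_, units = flat)
  rows[[length(rows) + 1L]] <- tibble::tibble(layer = "dense", side = NA_integer_, channels = NA_integer_, units = cfg$dense_width)
  rows[[length(rows) + 1L]] <- tibble::tibble(layer = "output", side = NA_integer_, channels = NA_integer_, units = 1L)
  dplyr::bind_rows(rows)
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities
#' clipped to `[eps, 1 - eps]`.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted probabilities, same length.
#' @param eps Clipping constant (default 1e-12).
#' @return Non-negative scalar.
#' @export
binary_cross_entropy <- function(labels, probs, eps = 1e-12) {
  if (length(labels) != length(probs)) {
    stop("`labels` (", length(labels), ") and `probs` (", length(probs), ") differ in length.", call. = FALSE)
  }
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

init_weights <- function(cfg) {
  # He-normal initialisation, zero biases
  weights <- list()
  c_in <- 1L
  for (b in seq_len(nrow(cfg$blocks))) {
    k <- cfg$blocks[b, 2]
    c_out <- cfg$blocks[b, 1]
    fan_in <- k * k * c_in
    weights[[length(weights) + 1L]] <- matrix(stats::rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)), c_out, fan_in)
    weights[[length(weights) + 1L]] <- numeric(c_out)
    c_in <- c_out
  }
  shapes <- layer_shapes(cfg)
  flat <- shapes$units[shapes$layer == "flatten"]
  weights[[length(weights) + 1L]] <- matrix(stats::rnorm(cfg$dense_width * flat, 0, sqrt(2 / flat)), cfg$dense_width, flat)
  weights[[length(weights) + 1L]] <- numeric(cfg$dense_width)
  weights[[length(weights) + 1L]] <- matrix(stats::rnorm(cfg$dense_width, 0, sqrt(2 / cfg$dense_width)), 1, cfg$dense_width)
  weights[[length(weights) + 1L]] <- numeric(1)
  weights
}

# Intensities arrive in [0, 1]; shift to [-0.5, 0.5] so the first
# convolution sees signed input (all-positive input invites uniform-sign
# first-layer gradients and ReLU die-off at this learning rate).
as_image_list <- function(images, input_side) {
  lapply(images, function(im) {
    if (inherits(im, "spectrogram_image")) im <- im$pixels
    if (!is.matrix(im) || nrow(im) != input_side || ncol(im) != input_side) {
      stop("Images must be ", input_side, " x ", input_side, " matrices.", call. = FALSE)
    }
    im - 0.5
  })
}

#' Train the spectrogram CNN
#'
#' Minimises binary cross-entropy by minibatch gradient descent (Adam by
#' default) over the architecture of [conv_net_config()]. Weight
#' initialisation, epoch shuffling and dropout are all driven by
#' `cfg$rng_seed`, so identical data and config reproduce the run exactly
#' (single-threaded).
#'
#' @param images List of `input_side` x `input_side` matrices in `[0, 1]`
#'   (or `spectrogram_image` objects), or the tibble from
#'   [spectrogram_images()] (its `image` column is used).
#' @param labels 0/1 vector (1 = patient) or the modality's class labels.
#' @param cfg A [conv_net_config()].
#' @return A `cnn_model`: list with `weights`, `cfg`, `history` (per-epoch
#'   tibble of `epoch`, `loss`, `accuracy`), `classes`.
#' @export
train_cnn <- function(images, labels = NULL, cfg = conv_net_config()) {
  if (is.data.frame(images)) {
    if (is.null(labels)) labels <- images$label
    images <- images$image
  }
  classes <- c("control", "patient")
  if (!is.numeric(labels)) {
    bad <- setdiff(unique(labels), classes)
    if (length(bad) > 0L) stop("Unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    y <- as.numeric(labels == "patient")
  } else {
    y <- as.numeric(labels)
  }
  stopifnot(length(y) == length(images), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("Training requires both classes to be present.", call. = FALSE)
  }
  imgs <- as_image_list(images, cfg$input_side)
  set.seed(cfg$rng_seed)
  weights <- init_weights(cfg)
  blocks <- matrix(as.integer(cfg$blocks), ncol = 3)
  n <- length(imgs)

  adam_m <- lapply(weights, function(w) w * 0)
  adam_v <- lapply(weights, function(w) w * 0)
  beta1 <- 0.9
  beta2 <- 0.999
  adam_eps <- 1e-8
  t_step <- 0L

  history <- tibble::tibble(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      res <- cnn_batch_grad(imgs[idx], y[idx], weights, blocks, cfg$dropout_rate)
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct + sum((res$probs >= 0.5) == (y[idx] == 1))
      t_step <- t_step + 1L
      for (w in seq_along(weights)) {
        g <- res$grads[[w]]
        if (cfg$optimizer == "adam") {
          adam_m[[w]] <- beta1 * adam_m[[w]] + (1 - beta1) * g
          adam_v[[w]] <- beta2 * adam_v[[w]] + (1 - beta2) * g^2
          mhat <- adam_m[[w]] / (1 - beta1^t_step)
          vhat <- adam_v[[w]] / (1 - beta2^t_step)
          weights[[w]] <- weights[[w]] - cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        } else {
          weights[[w]] <- weights[[w]] - cfg$learning_rate * g
        }
      }
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, loss = ep_loss / n, accuracy = ep_correct / n
    ))
  }
  structure(
    list(weights = weights, cfg = cfg, history = history, classes = classes),
    class = "cnn_model"
  )
}

#' Predict with a trained spectrogram CNN
#'
#' @param model A `cnn_model` from [train_cnn()].
#' @param images As in [train_cnn()].
#' @param threshold Probability cut for the positive (patient) class
#'   (default 0.5; labels are assigned by `probability >= threshold`).
#' @return A tibble with `prob` and `label`.
#' @export
predict_cnn <- function(model, images, threshold = 0.5) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.data.frame(images)) images <- images$image
  imgs <- as_image_list(images, model$cfg$input_side)
  blocks <- matrix(as.integer(model$cfg$blocks), ncol = 3)
  probs <- as.numeric(cnn_forward_batch(imgs, model$weights, blocks)$probs)
  tibble::tibble(
    prob = probs,
    label = ifelse(probs >= threshold, model$classes[2], model$classes[1])
  )
}

#' Learning-rate tuning curves
#'
#' Trains one model per candidate learning rate on the same data with the
#' same seed and returns the per-rate training histories, for side-by-side
#' accuracy/loss curve comparison.
#'
#' @inheritParams train_cnn
#' @param rates Numeric vector of learning rates (length >= 1).
#' @return A tibble with `learning_rate`, `epoch`, `loss`, `accuracy`.
#' @export
tune_learning_rate <- function(images, labels = NULL, rates, cfg = conv_net_config()) {
  stopifnot(length(rates) >= 1)
  purrr::map_dfr(rates, function(lr) {
    cfg_i <- cfg
    cfg_i$learning_rate <- lr
    fit <- train_cnn(images, labels, cfg_i)
    dplyr::mutate(fit$history, learning_rate = lr, .before = 1)
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(
    "<cnn_model>", nrow(x$cfg$blocks), "conv blocks, input",
    x$cfg$input_side, "x", x$cfg$input_side, "\n",
    sprintf("  trained %d epochs; final loss %.4f, accuracy %.3f\n", h$epoch, h$loss, h$accuracy)
  )
  invisible(x)
}

#' @rdname train_cnn
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @export
tidy.cnn_model <- function(x, ...) x$history

#' @rdname train_cnn
#' @export
glance.cnn_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = h$epoch, final_loss = h$loss, final_accuracy = h$accuracy,
    learning_rate = x$cfg$learning_rate, batch_size = x$cfg$batch_size,
    n_parameters = sum(vapply(x$weights, length, 1L))
  )
}
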