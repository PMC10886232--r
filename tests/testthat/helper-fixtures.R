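# Small in-code fixtures shared across test files.

small_sensory_cohort <- function(seed = 11, counts = c(non = 4, mi = 4, ms = 4)) {
  simulate_cohort(counts, "sensory", rng_seed = seed)
}

small_motor_cohort <- function(seed = 12, counts = c(control = 4, patient = 4)) {
  simulate_cohort(counts, "motor", rng_seed = seed)
}

# Naive O(n^2) DFT: the independent oracle for the FFT-based STFT.
naive_dft <- function(x) {
  n <- length(x)
  vapply(seq_len(n) - 1L, function(k) {
    sum(x * exp(-2i * pi * k * (seq_len(n) - 1L) / n))
  }, complex(1))
}

# Tiny fast CNN configuration for functional tests.
tiny_cnn_cfg <- function(...) {
  conv_net_config(
    input_side = 32, blocks = rbind(c(4, 3, 2), c(8, 3, 2)),
    dense_width = 16, dropout_rate = 0.25, learning_rate = 0.005,
    batch_size = 3, epochs = 4, rng_seed = 99, ...
  )
}

tiny_images <- function(n_per_class = 6, side = 32, seed = 5) {
  set.seed(seed)
  mk <- function(cl) {
    m <- matrix(stats::runif(side^2) * 0.2, side, side)
    if (cl == 1) m[3:10, 3:10] <- m[3:10, 3:10] + 0.7 else m[20:28, 20:28] <- m[20:28, 20:28] + 0.7
    m
  }
  list(
    images = c(
      lapply(seq_len(n_per_class), function(i) mk(0)),
      lapply(seq_len(n_per_class), function(i) mk(1))
    ),
    labels = rep(c(0, 1), each = n_per_class)
  )
}
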