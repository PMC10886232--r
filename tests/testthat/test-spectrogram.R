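test_that("frame counts follow floor((n - L)/hop) + 1 and frames are exact slices", {
  tr <- as.numeric(1:10)
  f <- frame_signal(tr, frame_length = 4, hop = 3)
  expect_equal(ncol(f), 3)
  expect_equal(f[, 1], 1:4)
  expect_equal(f[, 2], 4:7)
  expect_equal(f[, 3], 7:10)

  expect_equal(ncol(frame_signal(rnorm(2400), 120, 120)), 20)
  x <- rnorm(50)
  expect_equal(frame_signal(x, 50, 50)[, 1], x) # n = L -> one frame
  expect_error(frame_signal(rnorm(10), 11), "frame_length")

  set.seed(14)
  for (i in 1:20) {
    n <- sample(50:500, 1)
    L <- sample(2:n, 1)
    hop <- sample(1:L, 1)
    expect_equal(ncol(frame_signal(rnorm(n), L, hop)), (n - L) %/% hop + 1)
  }
})

test_that("stft matches a naive DFT-summation oracle on random 120-sample frames", {
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(120)
    X <- stft(x, frame_length = 120, hop = 120)
    oracle <- naive_dft(x * hann_window(120))[1:61]
    expect_lt(max(Mod(X[, 1] - oracle)) / max(Mod(oracle)), 1e-9)
  }
})

test_that("stft linearity and tone localisation hold", {
  expect_true(all(stft(rep(0, 2400)) == 0))
  cst <- stft(rep(3, 2400))
  expect_equal(unname(Mod(cst[1, ])), rep(3 * sum(hann_window(120)), 20), tolerance = 1e-9)
  # pure sinusoid at bin k of a 120-sample frame peaks at bin k
  for (k in c(5, 17, 40)) {
    tone <- cos(2 * pi * k * (0:119) / 120)
    X <- stft(tone, 120, 120)
    expect_equal(which.max(Mod(X[, 1])), k + 1)
  }
})

test_that("spectrogram power is the elementwise squared magnitude", {
  expect_equal(spectrogram_power(matrix(3 + 4i))$power[1, 1], 25)
  set.seed(2)
  x <- rnorm(240)
  X <- stft(x, 120, 120)
  sp <- spectrogram_power(X)
  expect_true(all(sp$power >= 0))
  # total power equals the naive oracle's sum over |DFT|^2 (one-sided bins)
  or <- naive_dft((x[1:120]) * hann_window(120))[1:61]
  expect_equal(sum(sp$power[, 1]), sum(Mod(or)^2), tolerance = 1e-9)
})

test_that("rendered images are 256 x 256, deterministic, and monotone in power", {
  set.seed(4)
  tr <- simulate_cmap(waveform_params(3, 8, c(0.9, 1.1), baseline_noise_sd = 0.1), rng_seed = 5)
  img1 <- render_spectrogram_image(spectrogram(tr))
  img2 <- render_spectrogram_image(spectrogram(tr))
  expect_equal(dim(img1$pixels), c(256L, 256L))
  expect_true(all(img1$pixels >= 0 & img1$pixels <= 1))
  expect_identical(img1$pixels, img2$pixels)

  # all-equal power -> constant 0.5 image with a warning
  zero_spec <- spectrogram(rep(0, 2400))
  expect_warning(imgz <- render_spectrogram_image(zero_spec), "Degenerate")
  expect_true(all(imgz$pixels == 0.5))

  # monotone: p1 >= p2 elementwise => intensities >= elementwise
  p2 <- matrix(runif(61 * 20), 61, 20)
  p1 <- p2 + matrix(runif(61 * 20), 61, 20)
  mk <- function(p) {
    structure(
      list(power = p, frame_length = 120, hop = 120, window = "hann", source_id = NA),
      class = "ncs_spectrogram"
    )
  }
  rng <- range(10 * log10(c(p1, p2) + 1e-12))
  i1 <- render_spectrogram_image(mk(p1), db_floor = rng[1], db_ceiling = rng[2])
  i2 <- render_spectrogram_image(mk(p2), db_floor = rng[1], db_ceiling = rng[2])
  expect_true(all(i1$pixels - i2$pixels >= -1e-12))
})

test_that("spectrogram_images maps a cohort to a shared-scale image table and PNG files", {
  co <- small_motor_cohort()
  out <- withr::local_tempdir()
  tbl <- spectrogram_images(co, out_dir = out)
  expect_equal(nrow(tbl), nrow(co))
  expect_s3_class(tbl$image[[1]], "spectrogram_image")
  scales <- vapply(tbl$image, function(i) i$db_floor, numeric(1))
  expect_equal(length(unique(scales)), 1L) # one global dB floor
  pngs <- list.files(out, pattern = "\\.png$")
  expect_length(pngs, nrow(co))
  px <- png::readPNG(file.path(out, pngs[1]))
  expect_equal(dim(px), c(256, 256))
})
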