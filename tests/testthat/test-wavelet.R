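test_that("haar_step computes pairwise half-sum and half-difference", {
  s <- haar_step(c(1, 3))
  expect_equal(s$approx, 2)
  expect_equal(s$detail, -1)
  expect_false(s$padded)

  const <- haar_step(rep(4.2, 10))
  expect_equal(const$approx, rep(4.2, 5))
  expect_equal(const$detail, rep(0, 5))

  expect_error(haar_step(1), "length >= 2")
})

test_that("haar_step is exactly invertible on random even-length input", {
  set.seed(42)
  for (n in c(2, 8, 100, 600)) {
    x <- rnorm(n)
    s <- haar_step(x)
    rec <- numeric(n)
    rec[seq(1, n, 2)] <- s$approx + s$detail
    rec[seq(2, n, 2)] <- s$approx - s$detail
    expect_equal(rec, x, tolerance = 1e-14)
  }
})

test_that("odd-length input repeats the last sample before pairing", {
  s <- haar_step(c(1, 3, 5))
  expect_true(s$padded)
  expect_equal(s$approx, c(2, 5))
  expect_equal(s$detail, c(-1, 0))
})

test_that("mwd matches a hand-recursed two-level oracle and depth-1 equals haar_step", {
  p <- mwd(c(1, 3, 2, 2, 4, 0, 1, 1), depth = 2)
  expect_equal(p$detail[[1]], c(-1, 0, 2, 0))
  expect_equal(p$detail[[2]], c(0, 0.5))
  expect_equal(p$approx, c(2, 1.5))

  set.seed(7)
  x <- rnorm(64)
  expect_equal(mwd(x, 1)$detail[[1]], haar_step(x)$detail)
  expect_equal(mwd(x, 1)$approx, haar_step(x)$approx)
})

test_that("mwd on a 1200-sample trace at depth 5 yields 6 sub-bands with correct lengths", {
  set.seed(1)
  x <- rnorm(1200)
  p <- mwd(x, 5)
  expect_length(p$detail, 5)
  # 1200 -> 600 -> 300 -> 150 -> 75 -> (pad) 38
  expect_equal(vapply(p$detail, length, 1L), c(600L, 300L, 150L, 75L, 38L))
  expect_length(p$approx, 38)
  expect_equal(p$padded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("pyramid inversion reproduces the input exactly for all depths", {
  set.seed(3)
  x <- rnorm(256)
  for (depth in c(1, 3, 5, 8)) {
    expect_equal(mwd_inverse(mwd(x, depth)), x, tolerance = 1e-14)
  }
  # padded case: inversion reproduces the padded series
  x_odd <- rnorm(75)
  rec <- mwd_inverse(mwd(x_odd, 1))
  expect_equal(rec, c(x_odd, x_odd[75]), tolerance = 1e-14)

  # interior-level padding (1200 -> ... -> 75 padded at level 5) still
  # reconstructs the even-length input exactly
  x_native <- rnorm(1200)
  expect_equal(mwd_inverse(mwd(x_native, 5)), x_native, tolerance = 1e-14)
})

test_that("sub-band length bookkeeping follows the ceil-halving rule", {
  set.seed(9)
  for (n in c(64, 100, 1200)) {
    x <- rnorm(n)
    for (depth in c(2, 5)) {
      p <- mwd(x, depth)
      lens <- vapply(p$detail, length, 1L)
      prev <- n
      for (z in seq_len(depth)) {
        expect_equal(lens[z], as.integer(ceiling(prev / 2)))
        expect_equal(p$padded[z], prev %% 2L == 1L)
        prev <- lens[z]
      }
      expect_length(p$approx, lens[depth])
    }
  }
  # without padding the sub-band lengths sum exactly to the input length
  p <- mwd(rnorm(1024), 5)
  expect_equal(sum(vapply(p$detail, length, 1L)) + length(p$approx), 1024L)
  expect_false(any(p$padded))
})

test_that("renyi_entropy matches the direct -log sum p^2 oracle at alpha 2", {
  set.seed(21)
  for (i in 1:10) {
    v <- rnorm(200)
    n_bins <- sample(c(8, 16, 32), 1)
    rng <- range(v)
    idx <- pmin(floor((v - rng[1]) / ((rng[2] - rng[1]) / n_bins)) + 1, n_bins)
    p <- tabulate(idx, n_bins) / length(v)
    expect_equal(renyi_entropy(v, alpha = 2, n_bins = n_bins), -log(sum(p^2)), tolerance = 1e-12)
  }
})

test_that("renyi_entropy handles degenerate and uniform mass correctly", {
  expect_equal(renyi_entropy(rep(3, 50)), 0) # all mass in one bin
  # exactly uniform over k occupied equal-mass bins -> log k for any alpha
  v <- rep(c(0.5, 1.5, 2.5, 3.5), each = 25) # 4 bins, equal mass
  for (alpha in c(0.5, 2, 3)) {
    expect_equal(renyi_entropy(v, alpha = alpha, n_bins = 4), log(4), tolerance = 1e-12)
  }
  expect_error(renyi_entropy(1:5, alpha = 1), "alpha")
  expect_error(renyi_entropy(1:5, alpha = -2), "alpha")
})

test_that("crossing_count follows the strict sign-change rule with zero inheritance", {
  expect_equal(crossing_count(c(1, 2, 3), 0), 0L)
  expect_equal(crossing_count(c(-1, 1, -1, 1), 0), 3L)
  expect_equal(crossing_count(c(0, 0, 1, -1), 0), 1L)
  expect_equal(crossing_count(c(1, 0, -1), 0), 1L) # zero takes previous sign
  expect_equal(crossing_count(c(1, 0, 1), 0), 0L)
  expect_equal(crossing_count(rep(0, 5), 0), 0L)
})

test_that("subband_features returns the 15 stated features with degenerate conventions", {
  f <- subband_features(c(5, 5, 5, 5))
  expect_length(f, 15)
  expect_named(f, c(
    "mean", "sd", "min", "max", "rms", "median", "skewness", "kurtosis",
    "p5", "p25", "p75", "p95", "zero_cross", "mean_cross", "renyi_entropy"
  ))
  expect_equal(unname(f[c("mean", "median", "min", "max", "rms", "p5", "p25", "p75", "p95")]), rep(5, 9))
  expect_equal(unname(f[c("sd", "skewness", "kurtosis", "zero_cross", "mean_cross", "renyi_entropy")]), rep(0, 6))

  g <- subband_features(c(-1, 1, -1, 1))
  expect_equal(unname(g["zero_cross"]), 3)
  expect_equal(unname(g["mean_cross"]), 3)
  expect_equal(unname(g["mean"]), 0)
  expect_equal(unname(g["rms"]), 1)
})

test_that("features are location- and scale-equivariant as expected", {
  set.seed(33)
  v <- rnorm(300, sd = 2)
  base <- subband_features(v)
  shift <- subband_features(v + 7)
  loc <- c("mean", "min", "max", "median", "p5", "p25", "p75", "p95")
  expect_equal(shift[loc], base[loc] + 7, tolerance = 1e-10)
  inv <- c("sd", "skewness", "kurtosis", "mean_cross", "renyi_entropy")
  expect_equal(shift[inv], base[inv], tolerance = 1e-10)

  scaled <- subband_features(v * 3)
  pos <- c("sd", "min", "max", "median", "p5", "p25", "p75", "p95", "rms", "mean")
  expect_equal(scaled[pos], base[pos] * 3, tolerance = 1e-10)
  inv2 <- c("skewness", "kurtosis", "zero_cross", "mean_cross", "renyi_entropy")
  expect_equal(scaled[inv2], base[inv2], tolerance = 1e-10)
})

test_that("hand_feature_vector is 90 median + 45 ulnar = 135 named entries", {
  set.seed(8)
  v <- hand_feature_vector(rnorm(1200), rnorm(1200))
  expect_length(v, 135)
  expect_equal(sum(startsWith(names(v), "median.")), 90)
  expect_equal(sum(startsWith(names(v), "ulnar.")), 45)
  expect_true(all(is.finite(v)))
  # documented ordering: median d1..d5,a5 then ulnar d1,d2,a2; 15 features each
  expect_equal(names(v)[1], "median.d1.mean")
  expect_equal(names(v)[15], "median.d1.renyi_entropy")
  expect_equal(names(v)[76], "median.a5.mean")
  expect_equal(names(v)[91], "ulnar.d1.mean")
  expect_equal(names(v)[135], "ulnar.a2.renyi_entropy")
})
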