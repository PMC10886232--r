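test_that("simulated traces have the native lengths and are seed-deterministic", {
  p <- waveform_params(2.2, 40, c(0.4, 0.6, 0.45), baseline_noise_sd = 1)
  t1 <- simulate_snap(p, rng_seed = 5)
  t2 <- simulate_snap(p, rng_seed = 5)
  expect_length(t1, 1200)
  expect_identical(t1, t2)
  expect_length(simulate_cmap(waveform_params(3, 8, c(0.9, 1.1)), 1), 2400)
})

test_that("zero amplitude and zero noise give an all-zero trace", {
  p <- waveform_params(2, 0, c(0.5, 0.5), baseline_noise_sd = 0)
  expect_equal(simulate_snap(p, 1), rep(0, 1200))
  expect_equal(simulate_cmap(p, 1), rep(0, 2400))
})

test_that("lobes exceeding the 6 ms sweep are rejected", {
  expect_error(waveform_params(5, 10, c(0.8, 0.8)), "6 ms")
})

test_that("severity delays and attenuates the peak over a seeded ensemble", {
  cls <- ncs_class_params("sensory", "strong")
  stat <- function(lab) {
    row <- cls[cls$label == lab, ]
    p <- waveform_params(row$lat_mean, row$amp_mean, row$durations[[1]],
      baseline_noise_sd = row$noise_sd, severity = lab
    )
    tr <- vapply(1:100, function(s) {
      x <- simulate_snap(p, rng_seed = s)
      c(which.max(abs(x)), max(abs(x)))
    }, numeric(2))
    rowMeans(tr)
  }
  s_non <- stat("non")
  s_ms <- stat("ms")
  expect_gt(s_ms[1], s_non[1]) # later |peak| position
  expect_lt(s_ms[2], s_non[2]) # smaller |peak|

  clsm <- ncs_class_params("motor", "strong")
  statm <- function(lab) {
    row <- clsm[clsm$label == lab, ]
    p <- waveform_params(row$lat_mean, row$amp_mean, row$durations[[1]],
      baseline_noise_sd = row$noise_sd, severity = lab
    )
    tr <- vapply(1:100, function(s) {
      x <- simulate_cmap(p, rng_seed = s)
      c(which.max(abs(x)), max(abs(x)))
    }, numeric(2))
    rowMeans(tr)
  }
  m_con <- statm("control")
  m_pat <- statm("patient")
  expect_gt(m_pat[1], m_con[1])
  expect_lt(m_pat[2], m_con[2])
})

test_that("class-conditional parameter means are ordered monotonically with severity", {
  for (sep in c("strong", "overlap")) {
    cls <- ncs_class_params("sensory", sep)
    expect_true(all(diff(cls$lat_mean) > 0)) # non < mi < ms latency
    expect_true(all(diff(cls$amp_mean) < 0)) # non > mi > ms amplitude
  }
})

test_that("simulate_cohort produces the requested counts with a full manifest", {
  co <- simulate_cohort(c(non = 19, mi = 21, ms = 36), "sensory", rng_seed = 2)
  expect_equal(nrow(co), 76 * 2) # two nerves per sensory hand
  expect_equal(dplyr::n_distinct(paste(co$subject_id, co$hand)), 76)
  expect_equal(sum(co$nerve == "median" & co$label == "ms"), 36)
  man <- cohort_manifest(co)
  expect_equal(nrow(man), nrow(co)) # one parameter draw per trace
  expect_true(all(c("onset_latency_ms", "peak_amplitude") %in% names(man)))

  empty <- simulate_cohort(c(control = 0, patient = 0), "motor", rng_seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_cohort(c(bogus = 3), "motor"), "bogus")
})

test_that("cohorts are deterministic under the seed", {
  a <- simulate_cohort(c(non = 3, mi = 3, ms = 3), "sensory", rng_seed = 77)
  b <- simulate_cohort(c(non = 3, mi = 3, ms = 3), "sensory", rng_seed = 77)
  expect_identical(a$trace, b$trace)
  expect_identical(cohort_manifest(a), cohort_manifest(b))
})

test_that("ulnar traces are unaffected by the hand's severity label", {
  co <- simulate_cohort(c(non = 100, ms = 100), "sensory", rng_seed = 31)
  man <- cohort_manifest(co)
  uln <- man[man$nerve == "ulnar", ]
  tt <- t.test(
    uln$onset_latency_ms[uln$label == "non"],
    uln$onset_latency_ms[uln$label == "ms"]
  )
  expect_gt(tt$p.value, 0.01) # fails to reject equal means
})

test_that("augmentation doubles the cohort and matches the prescribed noise level", {
  co <- simulate_cohort(c(control = 38, patient = 38), "motor", rng_seed = 9)
  aug <- augment_gaussian(co, noise_scale = 0.8, rng_seed = 4)
  expect_equal(nrow(aug), 152)
  expect_equal(sum(aug$provenance == "augmented"), 76)

  # noise_scale 0 -> exact duplicates
  aug0 <- augment_gaussian(co, noise_scale = 0, rng_seed = 4)
  expect_identical(aug0$trace[77:152], co$trace)

  # SD of (duplicate - original) ~ 0.8 x trace SD within 5% at 2400 samples
  d <- aug$trace[[77]] - co$trace[[1]]
  expect_equal(sd(d), 0.8 * sd(co$trace[[1]]), tolerance = 0.05)
})

test_that("the overlap preset does not allow perfect severity recovery", {
  co <- simulate_cohort(c(non = 20, mi = 20, ms = 20), "sensory",
    rng_seed = 13, separation = "overlap"
  )
  f <- featurize_cohort(co)
  cv <- cross_validate(f, "knn", k = 5, seed = 13)
  expect_lt(cv$mean_accuracy, 1)
})
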