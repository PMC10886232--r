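#' Waveform parameters for one simulated NCS trace
#'
#' A simulated action potential is a sum of signed Gaussian lobes (two for
#' motor CMAP, three for sensory SNAP morphology) placed after a flat
#' pre-onset baseline, normalised so the largest absolute excursion equals
#' `peak_amplitude`, with additive white Gaussian baseline noise. CTS
#' severity manifests as the clinically observed pattern: longer onset
#' latency and smaller amplitude.
#'
#' @param onset_latency_ms Onset of the response, ms (> 0).
#' @param peak_amplitude Peak absolute amplitude (uV scale for sensory, mV
#'   for motor; stored as given).
#' @param phase_durations_ms Positive vector of per-lobe durations, ms; the
#'   lobes are laid end to end from the onset. `onset_latency_ms +
#'   sum(phase_durations_ms)` must not exceed the 6 ms sweep.
#' @param lobe_amplitudes Signed relative lobe amplitudes (same length as
#'   `phase_durations_ms`).
#' @param baseline_noise_sd Noise standard deviation, same units as the
#'   trace.
#' @param severity Class label the trace belongs to.
#' @return A `waveform_params` list.
#' @export
waveform_params <- function(onset_latency_ms, peak_amplitude, phase_durations_ms,
                            lobe_amplitudes = NULL, baseline_noise_sd = 0,
                            severity = NA_character_) {
  if (is.null(lobe_amplitudes)) {
    lobe_amplitudes <- switch(as.character(length(phase_durations_ms)),
      "2" = c(1, -0.55),
      "3" = c(0.45, -1, 0.5),
      rep_len(c(1, -0.6), length(phase_durations_ms))
    )
  }
  stopifnot(
    onset_latency_ms > 0, peak_amplitude >= 0, all(phase_durations_ms > 0),
    length(lobe_amplitudes) == length(phase_durations_ms), baseline_noise_sd >= 0
  )
  if (onset_latency_ms + sum(phase_durations_ms) > 6) {
    stop(
      "Waveform exceeds the 6 ms sweep: onset ", round(onset_latency_ms, 3),
      " ms + lobes ", round(sum(phase_durations_ms), 3), " ms > 6 ms.",
      call. = FALSE
    )
  }
  structure(
    list(
      onset_latency_ms = onset_latency_ms, peak_amplitude = peak_amplitude,
      phase_durations_ms = phase_durations_ms, lobe_amplitudes = lobe_amplitudes,
      baseline_noise_sd = baseline_noise_sd, severity = severity
    ),
    class = "waveform_params"
  )
}

# Noise-free lobe sum on a time grid (ms), peak-normalised to amplitude.
waveform_shape <- function(params, t_ms) {
  edges <- params$onset_latency_ms + cumsum(c(0, params$phase_durations_ms))
  y <- numeric(length(t_ms))
  for (j in seq_along(params$phase_durations_ms)) {
    centre <- (edges[j] + edges[j + 1]) / 2
    sd_ms <- params$phase_durations_ms[j] / 4
    y <- y + params$lobe_amplitudes[j] * exp(-((t_ms - centre)^2) / (2 * sd_ms^2))
  }
  m <- max(abs(y))
  if (m > 0) y <- y / m * params$peak_amplitude
  y
}

simulate_trace <- function(params, n_samples, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  t_ms <- (seq_len(n_samples) - 1L) / n_samples * 6
  y <- waveform_shape(params, t_ms)
  if (params$baseline_noise_sd > 0) {
    y <- y + stats::rnorm(n_samples, 0, params$baseline_noise_sd)
  }
  y
}

#' Simulate one sensory nerve action potential (SNAP) trace
#'
#' Produces a 1200-sample, 6 ms sensory trace (one nerve) from
#' [waveform_params()]: flat pre-onset baseline, smooth triphasic lobes at
#' the given latency, additive Gaussian noise. Identical seed and parameters
#' give a bit-identical trace.
#'
#' @param params A `waveform_params`.
#' @param rng_seed Optional integer seed.
#' @return Numeric vector of length 1200.
#' @export
simulate_snap <- function(params, rng_seed = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  simulate_trace(params, ncs_n_samples("sensory"), rng_seed)
}

#' Simulate one compound motor action potential (CMAP) trace
#'
#' As [simulate_snap()] but 2400 samples (6 ms motor format) and mV-scale
#' amplitude.
#'
#' @inheritParams simulate_snap
#' @return Numeric vector of length 2400.
#' @export
simulate_cmap <- function(params, rng_seed = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  simulate_trace(params, ncs_n_samples("motor"), rng_seed)
}

#' Class-conditional waveform parameter distributions
#'
#' The documented configuration block behind [simulate_cohort()]: per class,
#' the mean and SD of onset latency and peak amplitude, the per-lobe
#' durations, and the baseline noise SD. Severity lengthens latency and
#' attenuates amplitude in the median nerve; the ulnar nerve always draws
#' from the healthy (`non`) row. Two presets are provided: `"strong"`
#' (well-separated classes, tight within-class spread) and `"overlap"`
#' (shifted means within one within-class SD and heavier noise, so classes
#' genuinely overlap).
#'
#' @param modality `"sensory"` or `"motor"`.
#' @param separation `"strong"` or `"overlap"`.
#' @return A tibble with one row per class: `label`, `lat_mean`, `lat_sd`
#'   (ms), `amp_mean`, `amp_sd` (uV sensory / mV motor), `noise_sd`,
#'   `durations` (list of per-lobe ms).
#' @export
ncs_class_params <- function(modality = c("sensory", "motor"),
                             separation = c("strong", "overlap")) {
  modality <- match.arg(modality)
  separation <- match.arg(separation)
  if (modality == "sensory") {
    dur <- list(c(0.40, 0.60, 0.45))
    if (separation == "strong") {
      tibble::tibble(
        label = c("non", "mi", "ms"),
        lat_mean = c(2.2, 3.0, 3.9), lat_sd = 0.15,
        amp_mean = c(40, 24, 10), amp_sd = c(4, 2.5, 1.2),
        noise_sd = 1.2, durations = dur
      )
    } else {
      tibble::tibble(
        label = c("non", "mi", "ms"),
        lat_mean = c(2.5, 2.8, 3.1), lat_sd = 0.55,
        amp_mean = c(34, 28, 22), amp_sd = 10,
        noise_sd = 4, durations = dur
      )
    }
  } else {
    dur <- list(c(0.7, 0.9))
    if (separation == "strong") {
      tibble::tibble(
        label = c("control", "patient"),
        lat_mean = c(3.0, 4.2), lat_sd = 0.12,
        amp_mean = c(8, 3.5), amp_sd = c(0.8, 0.4),
        noise_sd = 0.12, durations = dur
      )
    } else {
      tibble::tibble(
        label = c("control", "patient"),
        lat_mean = c(3.3, 3.7), lat_sd = 0.45,
        amp_mean = c(7, 5.5), amp_sd = 2,
        noise_sd = 0.5, durations = dur
      )
    }
  }
}

draw_params <- function(row) {
  total <- sum(row$durations[[1]])
  lat <- min(max(stats::rnorm(1, row$lat_mean, row$lat_sd), 0.5), 6 - total - 0.05)
  amp <- max(stats::rnorm(1, row$amp_mean, row$amp_sd), 0.05 * row$amp_mean)
  waveform_params(
    onset_latency_ms = lat, peak_amplitude = amp,
    phase_durations_ms = row$durations[[1]],
    baseline_noise_sd = row$noise_sd, severity = row$label
  )
}

#' Simulate a labelled NCS cohort
#'
#' Draws per-hand waveform parameters from the class-conditional
#' distributions of [ncs_class_params()] and simulates one record per hand:
#' sensory records get a severity-degraded median trace and an ulnar trace
#' always drawn from the healthy distribution (CTS spares the ulnar nerve);
#' motor records get a median trace only. Every parameter draw is recorded
#' in a manifest attached to the result.
#'
#' @param class_counts Named integer vector mapping class label to number of
#'   hands, e.g. `c(non = 19, mi = 21, ms = 36)` or
#'   `c(control = 19, patient = 57)`.
#' @param modality `"sensory"` or `"motor"`.
#' @param rng_seed Integer seed; the whole cohort is a deterministic
#'   function of it.
#' @param separation Class-separation preset, see [ncs_class_params()].
#' @return A validated signal tibble with provenance `"synthetic"`; the
#'   per-hand parameter draws are in `attr(, "manifest")` (also via
#'   [cohort_manifest()]).
#' @export
simulate_cohort <- function(class_counts, modality = c("sensory", "motor"),
                            rng_seed = 1L, separation = c("strong", "overlap")) {
  modality <- match.arg(modality)
  separation <- match.arg(separation)
  cls <- ncs_class_params(modality, separation)
  unknown <- setdiff(names(class_counts), cls$label)
  if (length(unknown) > 0L) {
    stop("Unknown label(s) for ", modality, " cohort: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(class_counts >= 0))
  set.seed(rng_seed)
  n_samp <- ncs_n_samples(modality)
  rows <- list()
  manifest <- list()
  idx <- 0L
  for (lab in cls$label[cls$label %in% names(class_counts)]) {
    crow <- cls[cls$label == lab, ]
    healthy <- cls[1, ] # first row is always the unaffected class
    for (h in seq_len(class_counts[[lab]])) {
      idx <- idx + 1L
      id <- sprintf("S%03d", idx)
      hand <- if (idx %% 2L == 1L) "right" else "left"
      pm <- draw_params(crow)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = id, hand = hand, nerve = "median", modality = modality,
        label = lab, provenance = "synthetic",
        trace = list(simulate_trace(pm, n_samp))
      )
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        subject_id = id, hand = hand, nerve = "median", label = lab,
        onset_latency_ms = pm$onset_latency_ms, peak_amplitude = pm$peak_amplitude,
        baseline_noise_sd = pm$baseline_noise_sd
      )
      if (modality == "sensory") {
        pu <- draw_params(healthy)
        pu$severity <- lab
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = id, hand = hand, nerve = "ulnar", modality = modality,
          label = lab, provenance = "synthetic",
          trace = list(simulate_trace(pu, n_samp))
        )
        manifest[[length(manifest) + 1L]] <- tibble::tibble(
          subject_id = id, hand = hand, nerve = "ulnar", label = lab,
          onset_latency_ms = pu$onset_latency_ms, peak_amplitude = pu$peak_amplitude,
          baseline_noise_sd = pu$baseline_noise_sd
        )
      }
    }
  }
  records <- if (length(rows) > 0L) dplyr::bind_rows(rows) else {
    tibble::tibble(
      subject_id = character(0), hand = character(0), nerve = character(0),
      modality = character(0), label = character(0), provenance = character(0),
      trace = list()
    )
  }
  validate_signal_table(records)
  attr(records, "manifest") <- if (length(manifest) > 0L) dplyr::bind_rows(manifest) else tibble::tibble()
  attr(records, "separation") <- separation
  attr(records, "rng_seed") <- rng_seed
  records
}

#' Parameter-draw manifest of a simulated cohort
#' @param records A tibble returned by [simulate_cohort()].
#' @return The manifest tibble of per-trace parameter draws.
#' @export
cohort_manifest <- function(records) {
  m <- attr(records, "manifest")
  if (is.null(m)) stop("No manifest attribute; was this table made by simulate_cohort()?", call. = FALSE)
  m
}

#' Gaussian-noise duplication augmentation
#'
#' Doubles a signal table: every record is kept and duplicated once, with
#' i.i.d. zero-mean Gaussian noise added to each trace of the duplicate.
#' The noise standard deviation is `noise_scale` times that trace's own
#' standard deviation (the "noise threshold of 0.8" interpretation).
#' Duplicates carry provenance `"augmented"` and a `-aug` subject-id suffix.
#'
#' @param records A signal tibble.
#' @param noise_scale Non-negative multiplier on the per-trace SD
#'   (default 0.8).
#' @param rng_seed Integer seed.
#' @return A signal tibble with `2 * nrow(records)` rows: originals first,
#'   then the augmented duplicates.
#' @export
augment_gaussian <- function(records, noise_scale = 0.8, rng_seed = 1L) {
  validate_signal_table(records)
  stopifnot(noise_scale >= 0)
  if (nrow(records) == 0L) return(records)
  set.seed(rng_seed)
  dup <- records
  dup$subject_id <- paste0(dup$subject_id, "-aug")
  dup$provenance <- "augmented"
  dup$trace <- lapply(records$trace, function(tr) {
    tr + stats::rnorm(length(tr), 0, noise_scale * stats::sd(tr))
  })
  out <- dplyr::bind_rows(records, dup)
  attr(out, "manifest") <- attr(records, "manifest")
  out
}
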