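#' Slice a trace into fixed-length analysis frames
#'
#' Frames are taken left to right starting at sample 1, advancing by `hop`
#' samples; the count is `floor((n - frame_length) / hop) + 1` and any
#' trailing remainder shorter than a frame is dropped. The defaults
#' (`frame_length = hop = 120`, no overlap) slice a 2400-sample motor trace
#' into exactly 20 frames.
#'
#' @param trace Numeric vector.
#' @param frame_length Samples per frame (default 120).
#' @param hop Samples between frame starts (default 120).
#' @return A `frame_length` x `n_frames` numeric matrix, one frame per column.
#' @export
frame_signal <- function(trace, frame_length = 120, hop = 120) {
  n <- length(trace)
  frame_length <- as.integer(frame_length)
  hop <- as.integer(hop)
  if (hop < 1L) stop("`hop` must be >= 1.", call. = FALSE)
  if (frame_length < 1L || frame_length > n) {
    stop("`frame_length` must be between 1 and length(trace) (", n, ").", call. = FALSE)
  }
  n_frames <- (n - frame_length) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  vapply(starts, function(s) trace[(s + 1L):(s + frame_length)], numeric(frame_length))
}

#' Periodic Hann window
#' @param n Window length in samples.
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

#' Short-time Fourier transform
#'
#' Multiplies each frame by a Hann window and applies the discrete Fourier
#' transform, retaining the one-sided spectrum (bins `0 .. frame_length/2`,
#' sufficient for real input).
#'
#' @inheritParams frame_signal
#' @param window Window type; only `"hann"` is implemented.
#' @return Complex matrix, `floor(frame_length/2) + 1` frequency bins (rows)
#'   by `n_frames` columns.
#' @export
stft <- function(trace, frame_length = 120, hop = 120, window = c("hann")) {
  window <- match.arg(window)
  frames <- frame_signal(trace, frame_length, hop)
  w <- hann_window(nrow(frames))
  X <- stats::mvfft(frames * w)
  X[seq_len(nrow(frames) %/% 2L + 1L), , drop = FALSE]
}

#' Spectrogram power matrix
#'
#' The elementwise squared magnitude `|X|^2` of an STFT matrix — the power
#' spectral density estimate that is rendered as the classifier's input
#' image. Stored frames-by-bins with metadata.
#'
#' @param X Complex STFT matrix (bins x frames) from [stft()].
#' @param frame_length,hop,source_id Metadata recorded on the result.
#' @return An object of class `ncs_spectrogram`: list with `power`
#'   (non-negative bins x frames matrix), `frame_length`, `hop`, `window`,
#'   `source_id`.
#' @export
spectrogram_power <- function(X, frame_length = 120, hop = 120, source_id = NA_character_) {
  structure(
    list(
      power = Mod(X)^2, frame_length = frame_length, hop = hop,
      window = "hann", source_id = source_id
    ),
    class = "ncs_spectrogram"
  )
}

#' Compute the power spectrogram of a trace
#'
#' Convenience composition of [stft()] and [spectrogram_power()].
#' @inheritParams stft
#' @param source_id Identifier stored on the result.
#' @return An `ncs_spectrogram`.
#' @export
spectrogram <- function(trace, frame_length = 120, hop = 120, source_id = NA_character_) {
  spectrogram_power(stft(trace, frame_length, hop),
    frame_length = frame_length, hop = hop, source_id = source_id
  )
}

#' @export
print.ncs_spectrogram <- function(x, ...) {
  cat(
    "<ncs_spectrogram>", nrow(x$power), "bins x", ncol(x$power), "frames,",
    "frame_length", x$frame_length, "hop", x$hop, "\n"
  )
  invisible(x)
}

# Deterministic bilinear resampling of a matrix onto an out_r x out_c grid,
# treating entries as samples at pixel centres.
bilinear_resize <- function(m, out_r, out_c) {
  in_r <- nrow(m)
  in_c <- ncol(m)
  map_axis <- function(out_n, in_n) {
    if (in_n == 1L) {
      list(lo = rep(1L, out_n), hi = rep(1L, out_n), w = rep(0, out_n))
    } else {
      pos <- (seq_len(out_n) - 0.5) / out_n * in_n - 0.5
      pos <- pmin(pmax(pos, 0), in_n - 1)
      lo <- floor(pos)
      list(lo = as.integer(lo) + 1L, hi = pmin(as.integer(lo) + 2L, in_n), w = pos - lo)
    }
  }
  r <- map_axis(out_r, in_r)
  cc <- map_axis(out_c, in_c)
  top <- m[r$lo, cc$lo, drop = FALSE] * (1 - cc$w[col(matrix(0, out_r, out_c))]) +
    m[r$lo, cc$hi, drop = FALSE] * cc$w[col(matrix(0, out_r, out_c))]
  bot <- m[r$hi, cc$lo, drop = FALSE] * (1 - cc$w[col(matrix(0, out_r, out_c))]) +
    m[r$hi, cc$hi, drop = FALSE] * cc$w[col(matrix(0, out_r, out_c))]
  top * (1 - r$w) + bot * r$w
}

#' Render a spectrogram as a fixed-size grayscale image
#'
#' Log-compresses power to decibels (`10 * log10(p + eps)`), clips to the
#' `[floor, ceiling]` dB range (by default the matrix's own range), min-max
#' scales to `[0, 1]`, and bilinearly resamples the bins x frames grid to a
#' `size` x `size` pixel image. Time runs left to right; frequency bin 0 is
#' at the bottom row of the image matrix as written to PNG (row 1 of the
#' returned matrix is the highest frequency, the PNG raster convention).
#' A degenerate all-equal matrix renders as a constant 0.5 image with a
#' warning.
#'
#' @param spec An `ncs_spectrogram`.
#' @param size Output side length in pixels (default 256).
#' @param eps Additive floor before the log (default 1e-12).
#' @param db_floor,db_ceiling Optional fixed clip range in dB; supply the
#'   training batch's global range for deterministic inference scaling.
#' @param file Optional path; when given the image is also written as 8-bit
#'   grayscale PNG.
#' @return An object of class `spectrogram_image`: list with `pixels`
#'   (`size` x `size` matrix in `[0, 1]`), `db_floor`, `db_ceiling`, `eps`,
#'   `source_id`.
#' @export
render_spectrogram_image <- function(spec, size = 256, eps = 1e-12,
                                     db_floor = NULL, db_ceiling = NULL,
                                     file = NULL) {
  stopifnot(inherits(spec, "ncs_spectrogram"))
  if (length(spec$power) == 0L) stop("Empty power matrix.", call. = FALSE)
  db <- 10 * log10(spec$power + eps)
  if (is.null(db_floor)) db_floor <- min(db)
  if (is.null(db_ceiling)) db_ceiling <- max(db)
  if (db_ceiling <= db_floor) {
    warning("Degenerate dB range (all-equal power); emitting constant 0.5 image.", call. = FALSE)
    scaled <- matrix(0.5, nrow(db), ncol(db))
  } else {
    scaled <- (pmin(pmax(db, db_floor), db_ceiling) - db_floor) / (db_ceiling - db_floor)
  }
  # rows: bins low->high; flip so row 1 of the image is the highest frequency
  img <- bilinear_resize(scaled[rev(seq_len(nrow(scaled))), , drop = FALSE], size, size)
  out <- structure(
    list(
      pixels = img, db_floor = db_floor, db_ceiling = db_ceiling, eps = eps,
      source_id = spec$source_id
    ),
    class = "spectrogram_image"
  )
  if (!is.null(file)) png::writePNG(img, target = file)
  out
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(
    "<spectrogram_image>", nrow(x$pixels), "x", ncol(x$pixels),
    sprintf("dB range [%.2f, %.2f]\n", x$db_floor, x$db_ceiling)
  )
  invisible(x)
}

#' Spectrogram images for a motor signal table
#'
#' Maps [spectrogram()] and [render_spectrogram_image()] over every median
#' trace of a motor signal tibble, using one global dB clip range (the
#' batch minimum/maximum) so all images share a deterministic intensity
#' scale.
#'
#' @param records A motor signal tibble (see [read_signal_table()]).
#' @param frame_length,hop,size,eps See [stft()] and
#'   [render_spectrogram_image()].
#' @param out_dir Optional directory; when given each image is written as
#'   `<subject_id>_<hand>.png`.
#' @return A tibble with columns `subject_id`, `hand`, `label`, `image`
#'   (list-column of `spectrogram_image`).
#' @export
spectrogram_images <- function(records, frame_length = 120, hop = 120,
                               size = 256, eps = 1e-12, out_dir = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  specs <- purrr::pmap(
    list(records$trace, records$subject_id, records$hand),
    function(tr, id, hand) spectrogram(tr, frame_length, hop, source_id = paste0(id, "_", hand))
  )
  dbs <- purrr::map(specs, ~ 10 * log10(.x$power + eps))
  db_floor <- min(purrr::map_dbl(dbs, min))
  db_ceiling <- max(purrr::map_dbl(dbs, max))
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  imgs <- purrr::map(specs, function(sp) {
    f <- if (is.null(out_dir)) NULL else file.path(out_dir, paste0(sp$source_id, ".png"))
    render_spectrogram_image(sp,
      size = size, eps = eps,
      db_floor = db_floor, db_ceiling = db_ceiling, file = f
    )
  })
  tibble::tibble(
    subject_id = records$subject_id, hand = records$hand,
    label = records$label, image = imgs
  )
}
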