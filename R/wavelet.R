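#' Single Haar analysis step (half-sum / half-difference)
#'
#' Splits a series into one approximation (low-pass) and one detail
#' (high-pass) sub-series by pairing consecutive non-overlapping samples:
#' `approx[k] = (x[2k-1] + x[2k]) / 2`, `detail[k] = (x[2k-1] - x[2k]) / 2`.
#' Note the `1/2` normalisation (pairwise mean and half-difference), not the
#' `1/sqrt(2)` of the orthonormal Haar DWT. An odd-length input has its last
#' sample repeated before pairing; the `padded` flag records this.
#'
#' @param x Numeric vector, length >= 2.
#' @return A list with `approx`, `detail` (each length `ceiling(length(x)/2)`)
#'   and logical `padded`.
#' @examples
#' haar_step(c(1, 3)) # approx 2, detail -1
#' @export
haar_step <- function(x) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("`x` must be a numeric vector of length >= 2.", call. = FALSE)
  }
  padded <- length(x) %% 2L == 1L
  if (padded) x <- c(x, x[length(x)])
  even <- x[seq(2L, length(x), by = 2L)]
  odd <- x[seq(1L, length(x), by = 2L)]
  list(approx = (odd + even) / 2, detail = (odd - even) / 2, padded = padded)
}

#' Multilevel Haar wavelet decomposition
#'
#' Recursively applies [haar_step()] to the approximation series, yielding a
#' pyramid of `depth` detail sub-bands `d1..d<depth>` (level 1 = highest
#' frequency) plus the final approximation `a<depth>`. This is the
#' decomposition used on sensory traces: depth 5 for the median nerve and
#' depth 2 for the ulnar nerve.
#'
#' @param x Numeric vector.
#' @param depth Integer >= 1, number of decomposition levels.
#' @return An object of class `wavelet_pyramid`: list with `detail` (list of
#'   numeric vectors `d1..d<depth>`), `approx` (numeric vector), `depth`, and
#'   `padded` (logical per level).
#' @examples
#' p <- mwd(c(1, 3, 2, 2, 4, 0, 1, 1), depth = 2)
#' p$detail[[1]] # -1 0 2 0
#' @export
mwd <- function(x, depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("`depth` must be a positive integer.", call. = FALSE)
  detail <- vector("list", depth)
  padded <- logical(depth)
  cur <- x
  for (z in seq_len(depth)) {
    s <- haar_step(cur)
    detail[[z]] <- s$detail
    padded[z] <- s$padded
    cur <- s$approx
  }
  structure(
    list(detail = detail, approx = cur, depth = depth, padded = padded),
    class = "wavelet_pyramid"
  )
}

#' Invert a Haar pyramid
#'
#' Exactly reconstructs the (per-level padded) input from a
#' [mwd()] decomposition via `x[2k-1] = a[k] + d[k]`, `x[2k-1+1] = a[k] - d[k]`
#' applied from the coarsest level upward. Used as the algebraic
#' reconstruction check; on unpadded inputs it reproduces the original
#' series bit-exactly.
#'
#' @param pyramid A `wavelet_pyramid`.
#' @return Numeric vector (length equals the padded input length).
#' @export
mwd_inverse <- function(pyramid) {
  stopifnot(inherits(pyramid, "wavelet_pyramid"))
  cur <- pyramid$approx
  for (z in rev(seq_len(pyramid$depth))) {
    d <- pyramid$detail[[z]]
    # a level that was padded reconstructs one synthetic trailing sample at
    # the scale below; drop it so lengths re-align with that level's detail
    cur <- cur[seq_along(d)]
    x <- numeric(2L * length(d))
    x[seq(1L, length(x), by = 2L)] <- cur + d
    x[seq(2L, length(x), by = 2L)] <- cur - d
    cur <- x
  }
  cur
}

#' @export
print.wavelet_pyramid <- function(x, ...) {
  cat("<wavelet_pyramid> depth", x$depth, "\n")
  lens <- c(vapply(x$detail, length, 1L), length(x$approx))
  names(lens) <- c(paste0("d", seq_len(x$depth)), paste0("a", x$depth))
  print(lens)
  invisible(x)
}

# Canonical per-sub-band feature order; names are stable API.
subband_feature_names <- c(
  "mean", "sd", "min", "max", "rms", "median", "skewness", "kurtosis",
  "p5", "p25", "p75", "p95", "zero_cross", "mean_cross", "renyi_entropy"
)

#' Renyi entropy of a histogram discretisation
#'
#' Bins `v` into `n_bins` equal-width bins over `[min(v), max(v)]` (all mass
#' in one bin when the range is zero) and returns the order-`alpha` Renyi
#' entropy `log(sum(p^alpha)) / (1 - alpha)` of the bin frequencies, natural
#' logarithm. At `alpha = 2` this is `-log(sum(p^2))`.
#'
#' @param v Numeric vector.
#' @param alpha Entropy order, `> 0` and `!= 1`. Default 2.
#' @param n_bins Number of histogram bins, `>= 2`. Default 16.
#' @return Non-negative scalar; 0 when all mass falls in one bin.
#' @export
renyi_entropy <- function(v, alpha = 2, n_bins = 16) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha == 1) {
    stop("`alpha` must be a single positive number != 1.", call. = FALSE)
  }
  if (n_bins < 2) stop("`n_bins` must be >= 2.", call. = FALSE)
  if (length(v) == 0L) stop("`v` must be non-empty.", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((v - rng[1]) / width) + 1L, n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(v)
  p <- p[p > 0]
  log(sum(p^alpha)) / (1 - alpha)
}

#' Level-crossing count
#'
#' Counts consecutive index pairs whose deviations from `level` have strictly
#' opposite sign. Samples exactly at `level` inherit the sign of the previous
#' non-zero deviation; leading at-level samples are ignored.
#'
#' @param v Numeric vector.
#' @param level Crossing level (0 for zero crossings, `mean(v)` for mean
#'   crossings).
#' @return Non-negative integer count.
#' @examples
#' crossing_count(c(-1, 1, -1, 1), 0) # 3
#' crossing_count(c(0, 0, 1, -1), 0) # 1
#' @export
crossing_count <- function(v, level = 0) {
  if (length(v) == 0L) stop("`v` must be non-empty.", call. = FALSE)
  s <- sign(v - level)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' The 15-feature summary of one wavelet sub-band
#'
#' Returns, in fixed order, the 12 statistical features — mean, standard
#' deviation (population, n denominator), min, max, root mean square, median,
#' skewness (Fisher g1), excess kurtosis (g2), and the 5th/25th/75th/95th
#' percentiles (linear interpolation) — and the 3 non-statistical features:
#' zero-crossing count, mean-crossing count, and Renyi entropy. Skewness and
#' kurtosis are defined as 0 for zero-variance input so vectors stay finite.
#'
#' @param v Numeric vector (a sub-band), non-empty.
#' @param alpha,n_bins Passed to [renyi_entropy()].
#' @return Named numeric vector of length 15.
#' @export
subband_features <- function(v, alpha = 2, n_bins = 16) {
  if (!is.numeric(v) || length(v) == 0L) stop("`v` must be a non-empty numeric vector.", call. = FALSE)
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 > 0) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- unname(stats::quantile(v, c(0.05, 0.25, 0.75, 0.95), type = 7))
  out <- c(
    mu, sqrt(m2), min(v), max(v), sqrt(mean(v^2)), stats::median(v),
    skew, kurt, q,
    crossing_count(v, 0), crossing_count(v, mu),
    renyi_entropy(v, alpha = alpha, n_bins = n_bins)
  )
  names(out) <- subband_feature_names
  out
}

#' Per-hand 135-element wavelet feature vector
#'
#' Decomposes the median sensory trace to depth 5 (6 sub-bands) and the ulnar
#' trace to depth 2 (3 sub-bands) and extracts [subband_features()] from every
#' sub-band: 6 x 15 = 90 median features followed by 3 x 15 = 45 ulnar
#' features, 135 in total. Names follow `{nerve}.{subband}.{feature}` with
#' sub-bands ordered `d1..dZ, aZ`.
#'
#' @param median_trace,ulnar_trace Numeric sensory traces (1200 samples each
#'   at the native 6 ms / 200 kHz format; any length >= 32 is accepted).
#' @param alpha,n_bins Renyi entropy configuration.
#' @param median_depth,ulnar_depth Decomposition depths (defaults 5 and 2).
#' @return Named numeric vector of length
#'   `(median_depth + 1 + ulnar_depth + 1) * 15` (135 at the defaults).
#' @export
hand_feature_vector <- function(median_trace, ulnar_trace, alpha = 2, n_bins = 16,
                                median_depth = 5, ulnar_depth = 2) {
  block <- function(trace, depth, nerve) {
    p <- mwd(trace, depth)
    bands <- c(p$detail, list(p$approx))
    names(bands) <- c(paste0("d", seq_len(depth)), paste0("a", depth))
    feats <- lapply(bands, subband_features, alpha = alpha, n_bins = n_bins)
    out <- unlist(feats, use.names = FALSE)
    names(out) <- as.vector(t(outer(
      paste0(nerve, ".", names(bands)), subband_feature_names, paste, sep = "."
    )))
    out
  }
  c(
    block(median_trace, median_depth, "median"),
    block(ulnar_trace, ulnar_depth, "ulnar")
  )
}
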