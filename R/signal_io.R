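#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Class labels per modality, fixed order used everywhere (confusion-matrix
# axes, factor levels, severity encoding).
ncs_class_order <- function(modality) {
  switch(modality,
    sensory = c("non", "mi", "ms"),
    motor = c("control", "patient"),
    stop("`modality` must be 'sensory' or 'motor'.", call. = FALSE)
  )
}

ncs_n_samples <- function(modality) {
  switch(modality, sensory = 1200L, motor = 2400L)
}

# Sampling rate implied by the fixed 6 ms / n-sample acquisition format.
ncs_sampling_hz <- function(modality) {
  ncs_n_samples(modality) / 6e-3
}

#' Validate an NCS signal table
#'
#' A signal table is a tibble with one row per nerve trace and columns
#' `subject_id`, `hand` (left/right), `nerve` (median/ulnar), `modality`
#' (sensory/motor), `label`, `provenance` (measured/synthetic/augmented) and
#' `trace` (list-column of numeric vectors). One *record* is a
#' (subject_id, hand) group. Invariants enforced:
#' sensory records carry both a median and an ulnar trace of exactly 1200
#' samples (6 ms at 200 kHz); motor records carry a median trace only, of
#' exactly 2400 samples (6 ms at 400 kHz); all voltages finite; labels drawn
#' from the modality's class set (`non`/`mi`/`ms` or `control`/`patient`).
#'
#' @param records A signal tibble.
#' @return `records`, invisibly, if valid; otherwise an error naming the
#'   offending record(s).
#' @export
validate_signal_table <- function(records) {
  need <- c("subject_id", "hand", "nerve", "modality", "label", "provenance", "trace")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("Signal table is missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  modality <- unique(records$modality)
  if (length(modality) > 1L) stop("Mixed modalities in one table: ", paste(modality, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) return(invisible(records))
  if (!modality %in% c("sensory", "motor")) stop("Unknown modality: ", modality, call. = FALSE)
  bad_label <- setdiff(unique(records$label), ncs_class_order(modality))
  if (length(bad_label) > 0L) {
    stop("Unknown ", modality, " label(s): ", paste(bad_label, collapse = ", "), call. = FALSE)
  }
  n_exp <- ncs_n_samples(modality)
  lens <- vapply(records$trace, length, 1L)
  finite <- vapply(records$trace, function(x) all(is.finite(x)), logical(1))
  bad <- which(lens != n_exp | !finite)
  if (length(bad) > 0L) {
    stop(
      "Invalid trace(s) for record(s) ",
      paste(unique(paste0(records$subject_id[bad], "/", records$hand[bad])), collapse = ", "),
      ": expected ", n_exp, " finite samples, got length(s) ",
      paste(unique(lens[bad]), collapse = ", "), ".",
      call. = FALSE
    )
  }
  per_rec <- split(records$nerve, paste0(records$subject_id, "/", records$hand))
  want <- if (modality == "sensory") c("median", "ulnar") else "median"
  ok <- vapply(per_rec, function(nv) identical(sort(unique(nv)), sort(want)) && !anyDuplicated(nv), logical(1))
  if (!all(ok)) {
    stop(
      "Record(s) with wrong nerve set for ", modality, " modality: ",
      paste(names(per_rec)[!ok], collapse = ", "),
      " (expected exactly: ", paste(want, collapse = " + "), ").",
      call. = FALSE
    )
  }
  invisible(records)
}

#' Read an NCS signal table from CSV
#'
#' The on-disk dialect is a long-form CSV with one row per nerve trace:
#' columns `subject_id,hand,nerve,label,provenance,v0..v{n-1}` (UTF-8, `.`
#' decimal, mandatory header), n = 1200 for sensory and 2400 for motor rows.
#'
#' @param path CSV path.
#' @param modality `"sensory"` or `"motor"`; fixes the expected trace length.
#' @return A validated signal tibble (see [validate_signal_table()]), row
#'   order preserved.
#' @export
read_signal_table <- function(path, modality = c("sensory", "motor")) {
  modality <- match.arg(modality)
  n_exp <- ncs_n_samples(modality)
  # voltages are read as text and converted with base strtod, which (unlike
  # the fast approximate CSV parser) round-trips %.17g output bit-exactly
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) != n_exp) {
    stop(
      "Expected ", n_exp, " voltage columns v0..v", n_exp - 1L, " for ",
      modality, " signals; found ", length(vcols), ".",
      call. = FALSE
    )
  }
  vcols <- paste0("v", seq_len(n_exp) - 1L) # enforce numeric order
  vchr <- as.matrix(df[vcols])
  vm <- matrix(suppressWarnings(as.numeric(vchr)), nrow = nrow(vchr))
  bad <- which(is.na(vm) & !(is.na(vchr) | vchr %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(
      "Non-numeric voltage value(s): first at row ", bad[1, 1],
      ", column ", vcols[bad[1, 2]], " ('", vchr[bad[1, , drop = FALSE]], "').",
      call. = FALSE
    )
  }
  records <- tibble::tibble(
    subject_id = df$subject_id, hand = df$hand, nerve = df$nerve,
    modality = modality, label = df$label, provenance = df$provenance,
    trace = lapply(seq_len(nrow(vm)), function(i) unname(vm[i, ]))
  )
  validate_signal_table(records)
  records
}

#' Write an NCS signal table to CSV
#'
#' Inverse of [read_signal_table()]: doubles are written with full
#' round-trip precision, so reading the file back reproduces the traces
#' bit-exactly.
#'
#' @param records A signal tibble sharing one modality.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(records, path) {
  validate_signal_table(records)
  if (nrow(records) == 0L) {
    writeLines("subject_id,hand,nerve,label,provenance", path)
    return(invisible(path))
  }
  vm <- do.call(rbind, records$trace)
  # %.17g guarantees a bit-exact double round trip through the text file
  vchr <- matrix(sprintf("%.17g", vm), nrow = nrow(vm))
  colnames(vchr) <- paste0("v", seq_len(ncol(vchr)) - 1L)
  out <- dplyr::bind_cols(
    dplyr::select(records, "subject_id", "hand", "nerve", "label", "provenance"),
    tibble::as_tibble(vchr)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a per-hand feature table to CSV
#'
#' One header row of feature names, one row per hand; `subject_id` and
#' `hand` lead, the class `label` is the final column. Input is either a
#' feature tibble (from [featurize_cohort()]) or a list of named feature
#' vectors plus parallel metadata, in which case all vectors must share one
#' name set and order.
#'
#' @param features Feature tibble with `subject_id`, `hand`, feature columns
#'   and `label`; or a list of equally named numeric vectors.
#' @param path Output CSV path.
#' @param subject_id,hand,label Metadata vectors, required when `features`
#'   is a list.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, subject_id = NULL, hand = NULL, label = NULL) {
  if (!is.data.frame(features)) {
    stopifnot(is.list(features))
    if (length(features) > 0L) {
      ref <- names(features[[1]])
      for (i in seq_along(features)) {
        di <- union(setdiff(names(features[[i]]), ref), setdiff(ref, names(features[[i]])))
        if (length(di) > 0L) {
          stop(
            "Feature vector ", i, " has an inconsistent name set; symmetric difference: ",
            paste(sort(di), collapse = ", "),
            call. = FALSE
          )
        }
      }
      features <- dplyr::bind_cols(
        tibble::tibble(subject_id = subject_id, hand = hand),
        tibble::as_tibble(do.call(rbind, lapply(features, function(v) v[ref]))),
        tibble::tibble(label = label)
      )
    } else {
      features <- tibble::tibble(
        subject_id = character(0), hand = character(0), label = character(0)
      )
    }
  }
  stopifnot(all(c("subject_id", "hand", "label") %in% names(features)))
  features <- dplyr::relocate(features, "subject_id", "hand") |>
    dplyr::relocate("label", .after = dplyr::last_col())
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A feature tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(), hand = readr::col_character(),
      label = readr::col_character(), .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
}

#' Wavelet feature table for a sensory cohort
#'
#' Applies [hand_feature_vector()] to every complete (median + ulnar) hand of
#' a sensory signal table, producing the 135-feature row per hand. Hands
#' missing either nerve trace are excluded with a warning, mirroring the
#' handling of incomplete clinical recordings.
#'
#' @param records A sensory signal tibble (complete hands; incomplete hands
#'   are dropped with a warning rather than an error).
#' @param alpha,n_bins Renyi entropy configuration (recorded as attributes
#'   `renyi_alpha`, `renyi_bins` on the result).
#' @return A feature tibble: `subject_id`, `hand`, 135 feature columns,
#'   `label`.
#' @export
featurize_cohort <- function(records, alpha = 2, n_bins = 16) {
  stopifnot(is.data.frame(records))
  wide <- tidyr::pivot_wider(
    dplyr::select(records, "subject_id", "hand", "label", "nerve", "trace"),
    names_from = "nerve", values_from = "trace"
  )
  if (!"ulnar" %in% names(wide)) wide$ulnar <- list(NULL)
  if (!"median" %in% names(wide)) wide$median <- list(NULL)
  complete <- vapply(seq_len(nrow(wide)), function(i) {
    !is.null(wide$median[[i]]) && !is.null(wide$ulnar[[i]])
  }, logical(1))
  if (any(!complete)) {
    warning(
      sum(!complete), " hand(s) lacking data from both nerves excluded: ",
      paste(paste0(wide$subject_id[!complete], "/", wide$hand[!complete]), collapse = ", "),
      call. = FALSE
    )
    wide <- wide[complete, , drop = FALSE]
  }
  feats <- purrr::map2(
    wide$median, wide$ulnar,
    ~ hand_feature_vector(.x, .y, alpha = alpha, n_bins = n_bins)
  )
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = wide$subject_id, hand = wide$hand),
    tibble::as_tibble(do.call(rbind, feats)),
    tibble::tibble(label = wide$label)
  )
  attr(out, "renyi_alpha") <- alpha
  attr(out, "renyi_bins") <- n_bins
  out
}
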