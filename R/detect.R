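# Detection: run every template over a preprocessed recording in its own
# montage; supra-threshold local-maximum matches that pass the template's
# property gates and classifier become nominations.

.NOMINATION_COLS <- c("recording_id", "template_id", "montage", "channel",
                      "start", "length", "start_s", "duration_s",
                      "correlation", "matching_variance",
                      "amplitude_difference", "background_ratio",
                      "reliability")

.empty_nominations <- function() {
  tibble::tibble(
    recording_id = character(), template_id = character(),
    montage = character(), channel = character(),
    start = integer(), length = integer(),
    start_s = numeric(), duration_s = numeric(),
    correlation = numeric(), matching_variance = numeric(),
    amplitude_difference = numeric(), background_ratio = numeric(),
    reliability = numeric()
  )
}

# nominations for one template against one derived recording, given cached
# channel FFTs; gating (bounds + classifier) optional
.detect_one <- function(rec, ffts, tpl_row, rel, threshold, gate) {
  waveform <- tpl_row$waveform[[1]]
  m <- length(waveform)
  fs <- rec$sample_rate
  traces <- .trace_all_channels(ffts, waveform)
  rows <- list()
  for (ci in seq_along(rec$channel_labels)) {
    cands <- .find_candidates(traces[, ci], m, threshold)
    for (i in cands) {
      epoch <- rec$signal[ci, i:(i + m - 1L)]
      preceding <- if (i > 1L) rec$signal[ci, max(1L, i - fs):(i - 1L)] else numeric()
      feats <- compute_match_features(epoch, preceding, waveform)
      if (gate) {
        X <- as.matrix(feats[, .FEATURE_NAMES])
        if (!.within_bounds(tpl_row$bounds[[1]], X)) next
        if (.classifier_score(tpl_row$classifier[[1]], X) <= 0) next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        recording_id = rec$recording_id,
        template_id = tpl_row$template_id,
        montage = rec$montage,
        channel = rec$channel_labels[ci],
        start = i - 1L, length = m,
        start_s = (i - 1L) / fs, duration_s = m / fs,
        correlation = feats$correlation,
        matching_variance = feats$matching_variance,
        amplitude_difference = feats$amplitude_difference,
        background_ratio = feats$background_ratio,
        reliability = rel
      )
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else .empty_nominations()
}

#' Detect IED nominations with a single template
#'
#' Slides the template over every channel of the (same-montage,
#' preprocessed) recording; candidate positions are local maxima of the
#' correlation trace above the threshold, thinned by non-maximum suppression
#' over one template length. With `gate = TRUE` each candidate must also lie
#' within the template's property bounds and be classified as an IED by its
#' linear SVM.
#'
#' @param rec A preprocessed `eeg_recording` in the template's montage.
#' @param tpl_row One-row template tibble (a row of `db$templates`).
#' @param threshold Correlation threshold (strict; default 0.85).
#' @param gate Apply property bounds + classifier (default TRUE).
#' @param reliability_value Reliability to stamp on the nominations.
#' @return Nomination tibble (possibly empty).
#' @export
detect_with_template <- function(rec, tpl_row, threshold = 0.85, gate = TRUE,
                                 reliability_value = NA_real_) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.null(tpl_row$montage) && rec$montage != tpl_row$montage) {
    stop("recording montage (", rec$montage,
         ") does not match template montage (", tpl_row$montage, ")")
  }
  ffts <- .channel_ffts(rec$signal)
  .detect_one(rec, ffts, tpl_row, reliability_value, threshold, gate)
}

#' Detect IED nominations with the whole database
#'
#' Derives the bipolar and Laplacian montages from the common-reference
#' recording, runs every template of the database over every channel of its
#' own montage, and concatenates the surviving nominations in a
#' deterministic order (montage, channel, start, template id).
#'
#' @param rec_common Preprocessed common-reference `eeg_recording` (100 Hz).
#' @param db A pruned `ied_template_db`.
#' @param threshold Correlation threshold.
#' @param gate Apply property/classifier gating.
#' @param config Montage table.
#' @return Nomination tibble with one row per template detection.
#' @export
detect_ieds <- function(rec_common, db, threshold = 0.85, gate = TRUE,
                        config = montage_config()) {
  stopifnot(inherits(rec_common, "eeg_recording"),
            inherits(db, "ied_template_db"))
  if (rec_common$montage != "common_reference") {
    stop("detection starts from a common-reference recording")
  }
  if (!nrow(db$templates)) {
    warning("empty template database: no nominations possible")
    return(.empty_nominations())
  }
  rel <- db_reliabilities(db)
  out <- list()
  for (mont in unique(db$templates$montage)) {
    rec_m <- derive_montage(rec_common, mont, config = config)
    ffts <- .channel_ffts(rec_m$signal)
    idx <- which(db$templates$montage == mont)
    for (ti in idx) {
      tpl_row <- db$templates[ti, ]
      out[[length(out) + 1L]] <- .detect_one(
        rec_m, ffts, tpl_row, unname(rel[tpl_row$template_id]),
        threshold, gate)
    }
  }
  noms <- dplyr::bind_rows(out)
  if (!nrow(noms)) return(.empty_nominations())
  dplyr::arrange(noms, .data$montage, .data$channel, .data$start,
                 .data$template_id)
}

#' Write / read nominations as CSV
#'
#' Persists nominations so detection can run ahead of time and the review
#' can load them later.
#'
#' @param noms Nomination tibble.
#' @param path CSV path.
#' @return `path` (write) or the nomination tibble (read).
#' @export
write_nominations <- function(noms, path) {
  utils::write.csv(noms[, .NOMINATION_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_nominations
#' @export
read_nominations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(.NOMINATION_COLS %in% names(df)))
  df$start <- as.integer(df$start)
  df$length <- as.integer(df$length)
  tibble::as_tibble(df)
}
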