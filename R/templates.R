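# Template extraction and match features.
# A template is one annotated spike-wave epoch on one channel in one
# montage, stored verbatim (after preprocessing) at 100 Hz.

.TEMPLATE_RANGE_S <- c(0.212, 0.860)
.FEATURE_NAMES <- c("correlation", "matching_variance",
                    "amplitude_difference", "background_ratio")

#' Extract template waveforms from annotated recordings
#'
#' One template is produced per (event, derived channel, montage) mark: for
#' each annotation (an electrode-level mark) and each requested montage, the
#' epoch is cut verbatim from every derived channel in which the annotated
#' electrode participates (a bipolar chain member, the electrode's own
#' laplacian/common-reference channel). Epochs outside the recording or
#' outside the 0.212-0.860 s duration range are skipped; skip reasons are
#' attached as the `"skipped"` attribute.
#'
#' @param recordings List of preprocessed (100 Hz) common-reference
#'   `eeg_recording`s.
#' @param annotations Annotation tibble with channel-level `"ied"` marks.
#' @param montages Montages to extract in.
#' @param config Montage table.
#' @return Tibble with columns `template_id`, `montage`, `channel`,
#'   `source_recording`, `onset_s`, `duration_s` and list-column `waveform`.
#' @export
extract_templates <- function(recordings, annotations,
                              montages = c("common_reference", "bipolar",
                                           "laplacian"),
                              config = montage_config()) {
  validate_annotations(annotations)
  ann <- dplyr::filter(annotations, .data$label == "ied", !is.na(.data$channel))
  recs <- stats::setNames(recordings,
                          vapply(recordings, `[[`, character(1), "recording_id"))
  skipped <- list()
  rows <- list()
  k <- 0L
  for (mont in montages) {
    derived <- lapply(recs, derive_montage, montage = mont, config = config)
    for (i in seq_len(nrow(ann))) {
      a <- ann[i, ]
      rec <- derived[[a$recording_id]]
      if (is.null(rec)) next
      fs <- rec$sample_rate
      if (a$duration_s < .TEMPLATE_RANGE_S[1] ||
          a$duration_s > .TEMPLATE_RANGE_S[2]) {
        skipped[[length(skipped) + 1L]] <- sprintf(
          "%s @%.3fs: duration %.3fs outside template range",
          a$recording_id, a$onset_s, a$duration_s)
        next
      }
      start <- round(a$onset_s * fs) + 1L
      len <- round(a$duration_s * fs)
      if (start < 1L || start + len - 1L > rec_n_samples(rec)) {
        skipped[[length(skipped) + 1L]] <- sprintf(
          "%s @%.3fs: epoch outside recording", a$recording_id, a$onset_s)
        next
      }
      carriers <- Filter(
        function(ch) a$channel %in% channel_electrodes(ch, mont),
        rec$channel_labels
      )
      for (ch in carriers) {
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          template_id = sprintf("tpl-%05d", k),
          montage = mont, channel = ch,
          source_recording = a$recording_id,
          onset_s = a$onset_s, duration_s = len / fs,
          waveform = list(as.numeric(rec$signal[ch, start:(start + len - 1L)]))
        )
      }
    }
  }
  out <- if (k) dplyr::bind_rows(rows) else tibble::tibble(
    template_id = character(), montage = character(), channel = character(),
    source_recording = character(), onset_s = numeric(),
    duration_s = numeric(), waveform = list()
  )
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Match features between a detected epoch and a template
#'
#' The feature vector a template's classifier sees for each supra-threshold
#' detection:
#' * `correlation` — Pearson correlation between epoch and template;
#' * `matching_variance` — variance of the residual after scaling the
#'   (centred) template onto the epoch by its least-squares gain, in uV^2;
#' * `amplitude_difference` — absolute difference of peak-to-peak
#'   amplitudes, in uV;
#' * `background_ratio` — epoch RMS divided by the RMS of up to 1 s of
#'   signal preceding the epoch (1 when no preceding signal exists).
#'
#' @param epoch Numeric vector, same length as the template waveform.
#' @param preceding Numeric vector of signal immediately before the epoch
#'   (up to 1 s; may be empty).
#' @param waveform Template waveform vector.
#' @return One-row tibble with the four features and a `degenerate` flag
#'   (zero-variance epoch or missing preceding segment).
#' @export
compute_match_features <- function(epoch, preceding, waveform) {
  m <- length(waveform)
  stopifnot(length(epoch) == m)
  t0 <- waveform - mean(waveform)
  e0 <- epoch - mean(epoch)
  tt <- sum(t0^2)
  ee <- sum(e0^2)
  degenerate <- FALSE
  if (ee <= 1e-12 * m || tt <= 1e-12 * m) {
    corr <- 0
    gain <- 0
    degenerate <- TRUE
  } else {
    corr <- sum(e0 * t0) / sqrt(ee * tt)
    gain <- sum(e0 * t0) / tt
  }
  resid <- e0 - gain * t0
  mv <- sum(resid^2) / max(m - 1L, 1L)
  ad <- abs(diff(range(epoch)) - diff(range(waveform)))
  if (length(preceding) >= 2) {
    pre_rms <- sqrt(mean(preceding^2))
    ep_rms <- sqrt(mean(epoch^2))
    br <- if (pre_rms > 0) ep_rms / pre_rms else 0
    if (pre_rms == 0) degenerate <- TRUE
  } else {
    br <- 1
    degenerate <- TRUE
  }
  tibble::tibble(
    correlation = corr, matching_variance = mv,
    amplitude_difference = ad, background_ratio = br,
    degenerate = degenerate
  )
}
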