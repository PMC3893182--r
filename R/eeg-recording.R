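#' @keywords internal
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Canonical 10-20 electrode order
#'
#' The 19 scalp electrodes of the international 10-20 system, in the fixed
#' order used throughout the package. Recordings read from disk are reordered
#' to this sequence so that montage derivations and channel indices are stable.
#'
#' @return Character vector of 19 electrode labels.
#' @export
electrodes_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Construct an EEG recording object
#'
#' A recording is a channels-by-samples matrix of microvolt values plus the
#' metadata needed to interpret it. All channels share one sample rate and one
#' length. The montage tag records which derivation the rows currently
#' represent: `"common_reference"` (raw referential electrodes), `"bipolar"`
#' (longitudinal double-banana chains) or `"laplacian"` (each electrode minus
#' the mean of its 10-20 neighbours).
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param channel_labels Character vector, one label per row of `signal`.
#' @param sample_rate Sampling rate in Hz (positive scalar).
#' @param montage One of `"common_reference"`, `"bipolar"`, `"laplacian"`.
#' @param recording_id Opaque identifier string.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, channel_labels, sample_rate,
                          montage = "common_reference",
                          recording_id = "unnamed") {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(
    is.numeric(signal),
    length(channel_labels) == nrow(signal),
    is.numeric(sample_rate), length(sample_rate) == 1L, sample_rate > 0
  )
  montage <- match.arg(montage, c("common_reference", "bipolar", "laplacian"))
  rownames(signal) <- channel_labels
  structure(
    list(
      signal = signal,
      channel_labels = as.character(channel_labels),
      sample_rate = as.numeric(sample_rate),
      montage = montage,
      recording_id = as.character(recording_id)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording '%s'>  %d channels x %d samples @ %g Hz (%.1f s), montage: %s\n",
    x$recording_id, nrow(x$signal), ncol(x$signal), x$sample_rate,
    ncol(x$signal) / x$sample_rate, x$montage
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$signal)

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$signal) / rec$sample_rate

#' Number of samples per channel
#' @param rec An `eeg_recording`.
#' @return Integer sample count.
#' @export
rec_n_samples <- function(rec) ncol(rec$signal)

#' Tidy an EEG recording into long format
#'
#' Returns one row per (channel, sample) with the time in seconds, convenient
#' for plotting with ggplot2.
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time_s`, `amplitude_uv`.
#' @export
tidy.eeg_recording <- function(x, ...) {
  n <- ncol(x$signal)
  tibble::tibble(
    channel = rep(x$channel_labels, each = n),
    time_s = rep(seq_len(n) - 1, times = nrow(x$signal)) / x$sample_rate,
    amplitude_uv = as.vector(t(x$signal))
  )
}

#' Plot an EEG recording as stacked traces
#'
#' @param object An `eeg_recording`.
#' @param channels Optional subset of channel labels to show.
#' @param offset_uv Vertical offset between traces in microvolts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_recording <- function(object, channels = NULL, offset_uv = 150, ...) {
  df <- tidy.eeg_recording(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  labs <- unique(df$channel)
  df$offset <- offset_uv * (length(labs) - match(df$channel, labs))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_s, y = .data$amplitude_uv + .data$offset,
    group = .data$channel
  )) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::scale_y_continuous(
      breaks = offset_uv * (length(labs) - seq_along(labs)), labels = labs
    ) +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("%s (%s)", object$recording_id, object$montage)
    ) +
    ggplot2::theme_minimal()
}
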