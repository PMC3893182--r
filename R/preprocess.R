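#' Load a montage configuration
#'
#' Reads the YAML table defining the longitudinal bipolar chain and the
#' Laplacian neighbour sets. The package ships a default table for the
#' 19-electrode 10-20 layout; pass a path to substitute your own.
#'
#' @param path Optional path to a YAML file with `bipolar` (list of
#'   electrode pairs) and `laplacian` (electrode -> neighbour list) entries.
#' @return A list with elements `bipolar` and `laplacian`.
#' @export
montage_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montages.yaml", package = "iedreview")
  }
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$bipolar), !is.null(cfg$laplacian))
  cfg
}

#' Band-pass filter and resample a recording
#'
#' The standard preprocessing chain applied before template extraction and
#' detection: a zero-phase 4th-order Butterworth band-pass (default
#' 0.5-30 Hz, applied forward-backward so event onsets are not shifted),
#' followed by resampling to the working rate of 100 Hz. All template and
#' detection arithmetic in the package assumes this 100 Hz grid.
#'
#' @param rec An `eeg_recording` at native rate (>= 100 Hz).
#' @param band Length-2 numeric, band-pass edges in Hz.
#' @param target_rate Output sampling rate in Hz.
#' @return The filtered recording resampled to `target_rate`.
#' @export
preprocess <- function(rec, band = c(0.5, 30), target_rate = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sample_rate < target_rate) {
    stop("native sample rate (", rec$sample_rate,
         " Hz) is below the target rate (", target_rate, " Hz)")
  }
  ny <- rec$sample_rate / 2
  bf <- signal::butter(4, band / ny, type = "pass")
  filtered <- t(apply(rec$signal, 1L, function(ch) {
    as.numeric(signal::filtfilt(bf, ch))
  }))
  if (rec$sample_rate != target_rate) {
    frac <- .as_fraction(target_rate / rec$sample_rate)
    filtered <- t(apply(filtered, 1L, function(ch) {
      as.numeric(signal::resample(ch, frac[1], frac[2]))
    }))
  }
  eeg_recording(filtered, rec$channel_labels, target_rate,
                montage = rec$montage, recording_id = rec$recording_id)
}

# rational approximation p/q of a resampling ratio
.as_fraction <- function(x, max_den = 1024L) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("cannot express resampling ratio ", x, " as a small fraction")
}

#' Derive a review montage from a common-reference recording
#'
#' Review takes place in three montages. `common_reference` is the identity.
#' `bipolar` forms the longitudinal double-banana chains (Fp1-F7, F7-T3, ...),
#' each derived channel being the difference of its two electrodes.
#' `laplacian` subtracts from each electrode the mean of its 10-20 neighbours,
#' sharpening focal activity. Both tables come from [montage_config()].
#'
#' @param rec A common-reference `eeg_recording`.
#' @param montage Target montage name.
#' @param config Montage table, as returned by [montage_config()].
#' @return An `eeg_recording` in the requested montage. Bipolar channels are
#'   labelled `"A-B"`; laplacian channels keep their electrode label.
#' @export
derive_montage <- function(rec, montage, config = montage_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$montage != "common_reference") {
    stop("montage derivation starts from a common-reference recording")
  }
  montage <- as.character(montage)
  if (montage == "common_reference") return(rec)
  if (montage == "bipolar") {
    pairs <- config$bipolar
    missing <- setdiff(unique(unlist(pairs)), rec$channel_labels)
    if (length(missing)) stop("missing electrodes: ", paste(missing, collapse = ", "))
    sig <- do.call(rbind, lapply(pairs, function(p) {
      rec$signal[p[[1]], ] - rec$signal[p[[2]], ]
    }))
    labs <- vapply(pairs, function(p) paste0(p[[1]], "-", p[[2]]), character(1))
    return(eeg_recording(sig, labs, rec$sample_rate, "bipolar", rec$recording_id))
  }
  if (montage == "laplacian") {
    nb <- config$laplacian
    labs <- intersect(rec$channel_labels, names(nb))
    if (!length(labs)) stop("no electrodes with a laplacian neighbour entry")
    sig <- do.call(rbind, lapply(labs, function(e) {
      nbs <- intersect(unlist(nb[[e]]), rec$channel_labels)
      if (!length(nbs)) stop("electrode ", e, " has no available neighbours")
      rec$signal[e, ] - colMeans(rec$signal[nbs, , drop = FALSE])
    }))
    return(eeg_recording(sig, labs, rec$sample_rate, "laplacian", rec$recording_id))
  }
  stop("unknown montage: '", montage, "'")
}

#' Electrodes participating in a montage channel
#'
#' Maps a derived channel label back to the referential electrodes it is
#' built from: `"F3-C3"` -> F3, C3 (bipolar); a laplacian or common-reference
#' channel maps to its own electrode. Used to relate electrode-level
#' annotations to derived channels.
#'
#' @param channel Channel label.
#' @param montage Montage the label belongs to.
#' @return Character vector of electrode labels.
#' @export
channel_electrodes <- function(channel, montage) {
  if (montage == "bipolar") strsplit(channel, "-", fixed = TRUE)[[1]] else channel
}
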