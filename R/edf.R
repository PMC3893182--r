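# Minimal EDF (European Data Format) reader/writer.
# EDF: 256-byte fixed header, 256 bytes per signal header, then data records
# of little-endian 16-bit integers, one block per signal per record.
# Physical values are mapped linearly onto the digital range per channel.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_read_field <- function(con, width, n = 1L) {
  vapply(seq_len(n), function(i) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }, character(1))
}

#' Write a recording to an EDF file
#'
#' Writes a common-reference recording as EDF with one-second data records
#' and per-channel physical scaling onto the 16-bit digital range. The sample
#' rate must be a whole number; a trailing partial second is truncated with a
#' warning (EDF stores whole records only).
#'
#' @param rec An `eeg_recording` (common reference).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sample rate")
  fs <- as.integer(round(fs))
  n <- ncol(rec$signal)
  n_rec <- n %/% fs
  if (n_rec * fs != n) {
    warning("truncating trailing partial data record (",
            n - n_rec * fs, " samples)")
  }
  ns <- nrow(rec$signal)
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  pmax <- apply(abs(sig), 1L, max)
  pmax <- ifelse(pmax < 1e-6, 1, pmax * 1.0001)
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad(paste("Startdate 01-JAN-2000", rec$recording_id), 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256L * (1L + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad("1", 8),
    .edf_pad(ns, 4)
  ), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, .edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(paste("EEG", rec$channel_labels), 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", -pmax), 8)
  field(sprintf("%.6g", pmax), 8)
  field(rep(-dmax, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  # digital samples, record-interleaved by channel
  scale <- dmax / pmax
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(sig[ch, idx] * scale[ch]))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads an EDF/EDF+ file, converts digital values back to physical units,
#' normalizes channel labels (an `"EEG "` prefix and `"-REF"`/`"-LE"`
#' suffixes are stripped) and reorders channels to the canonical 10-20
#' sequence of [electrodes_1020()]. Channels outside the required set are
#' dropped; a missing required electrode is an error naming it.
#'
#' @param path EDF file path.
#' @param required Electrode labels the file must contain (default the
#'   19-channel 10-20 set). Order of this vector is the output channel order.
#' @return A common-reference `eeg_recording` at the file's native rate.
#' @export
read_edf <- function(path, required = electrodes_1020()) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_read_field(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(.edf_read_field(con, 80)) # patient
  rec_field <- .edf_read_field(con, 80)
  invisible(.edf_read_field(con, 8)); invisible(.edf_read_field(con, 8))
  invisible(.edf_read_field(con, 8)); invisible(.edf_read_field(con, 44))
  n_rec <- as.integer(.edf_read_field(con, 8))
  rec_dur <- as.numeric(.edf_read_field(con, 8))
  ns <- as.integer(.edf_read_field(con, 4))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count")

  labels <- .edf_read_field(con, 16, ns)
  invisible(.edf_read_field(con, 80, ns)) # transducer
  invisible(.edf_read_field(con, 8, ns))  # dimension
  pmin <- as.numeric(.edf_read_field(con, 8, ns))
  pmax <- as.numeric(.edf_read_field(con, 8, ns))
  dmin <- as.numeric(.edf_read_field(con, 8, ns))
  dmax <- as.numeric(.edf_read_field(con, 8, ns))
  invisible(.edf_read_field(con, 80, ns)) # prefiltering
  spr <- as.integer(.edf_read_field(con, 8, ns))
  invisible(.edf_read_field(con, 32, ns))
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)) || n_rec < 0L) {
    stop("corrupt EDF header: unparsable signal fields")
  }

  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[ch]) stop("truncated EDF data section")
      phys <- pmin[ch] + (dig - dmin[ch]) *
        (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- phys
    }
  }

  clean <- gsub("^EEG[ _]*", "", labels)
  clean <- gsub("[-_ ](REF|LE|AVG)$", "", clean, ignore.case = TRUE)
  clean <- trimws(clean)
  missing <- setdiff(required, clean)
  if (length(missing)) {
    stop("EDF file is missing required electrodes: ",
         paste(missing, collapse = ", "))
  }
  keep <- match(required, clean)
  rid <- sub("^Startdate [^ ]+ ?", "", rec_field)
  if (!nzchar(rid)) rid <- basename(path)
  eeg_recording(data[keep, , drop = FALSE], required,
                sample_rate = spr[1] / rec_dur,
                montage = "common_reference", recording_id = rid)
}
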