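#' Event annotation tables
#'
#' Annotations are plain tibbles with one row per marked event:
#' `recording_id`, `channel` (electrode label, or `NA` when only onset and
#' duration were marked, as is typical for evaluation marks), `onset_s`,
#' `duration_s` (seconds from recording start) and `label` (one of `"ied"`,
#' `"rejected"`, `"unsure"`). On disk they are a comma-separated file with a
#' header row and onsets printed with millisecond precision.
#'
#' @param recording_id,channel,onset_s,duration_s,label Column vectors
#'   (recycled to a common length).
#' @return A validated annotation tibble.
#' @export
annotation_table <- function(recording_id = character(), channel = NA_character_,
                             onset_s = numeric(), duration_s = numeric(),
                             label = "ied") {
  df <- tibble::tibble(
    recording_id = as.character(recording_id),
    channel = as.character(channel),
    onset_s = as.numeric(onset_s),
    duration_s = as.numeric(duration_s),
    label = as.character(label)
  )
  validate_annotations(df)
  df
}

validate_annotations <- function(df) {
  stopifnot(all(c("recording_id", "channel", "onset_s", "duration_s", "label")
                %in% names(df)))
  if (nrow(df)) {
    stopifnot(all(df$onset_s >= 0), all(df$duration_s > 0),
              all(df$label %in% c("ied", "rejected", "unsure")))
  }
  invisible(df)
}

#' Write annotations to CSV
#'
#' @param events Annotation tibble (see [annotation_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  validate_annotations(events)
  out <- dplyr::mutate(events,
    onset_s = sprintf("%.3f", .data$onset_s),
    duration_s = sprintf("%.3f", .data$duration_s)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read annotations from CSV
#'
#' @param path CSV path as written by [write_annotations()].
#' @return Annotation tibble.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          recording_id = "character", channel = "character",
                          onset_s = "numeric", duration_s = "numeric",
                          label = "character"
                        ))
  df$channel[df$channel == "" | df$channel == "NA"] <- NA_character_
  validate_annotations(tibble::as_tibble(df))
}
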