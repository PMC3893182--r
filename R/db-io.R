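# Versioned single-file JSON container for the template database.
# Numeric fields are written at full precision so a round trip is lossless.

.DB_FORMAT <- "iedreview-template-db"
.DB_VERSION <- 1L

#' Save a template database
#'
#' Writes a versioned JSON container holding every template (waveform,
#' counts, classifier parameters, property bounds) and the build metadata.
#'
#' @param db An `ied_template_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_template_db <- function(db, path) {
  stopifnot(inherits(db, "ied_template_db"))
  t <- db$templates
  tpl_list <- lapply(seq_len(nrow(t)), function(i) {
    clf <- t$classifier[[i]]
    b <- t$bounds[[i]]
    list(
      template_id = t$template_id[i],
      montage = t$montage[i],
      channel = t$channel[i],
      source_recording = t$source_recording[i],
      onset_s = t$onset_s[i],
      duration_s = t$duration_s[i],
      true_count = t$true_count[i],
      false_count = t$false_count[i],
      waveform = I(t$waveform[[i]]),
      classifier = if (is.null(clf)) NULL else lapply(clf, I),
      bounds = if (is.null(b)) NULL else
        list(features = I(colnames(b)), lo = I(unname(b["lo", ])),
             hi = I(unname(b["hi", ])))
    )
  })
  payload <- list(
    format = .DB_FORMAT, version = .DB_VERSION,
    smoothing = db$smoothing, metadata = db$metadata,
    templates = tpl_list
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a template database
#'
#' @param path File written by [save_template_db()].
#' @return An `ied_template_db`; a wrong format or version is an explicit
#'   error, never a silently empty database.
#' @export
load_template_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("corrupted template database file: ",
                             conditionMessage(e))
  )
  if (!identical(payload$format, .DB_FORMAT)) {
    stop("not a template database file (format field missing or wrong)")
  }
  if (!identical(as.integer(payload$version), .DB_VERSION)) {
    stop("template database version ", payload$version,
         " not supported (expected ", .DB_VERSION, ")")
  }
  rows <- lapply(payload$templates, function(tp) {
    clf <- tp$classifier
    if (!is.null(clf)) {
      clf <- lapply(clf, function(x) {
        if (is.list(x)) unlist(x) else x
      })
      if (!is.null(clf$w)) {
        clf$w <- as.numeric(clf$w)
        clf$b <- as.numeric(clf$b)
        clf$center <- stats::setNames(as.numeric(clf$center), .FEATURE_NAMES)
        clf$scale <- stats::setNames(as.numeric(clf$scale), .FEATURE_NAMES)
      }
    }
    b <- tp$bounds
    if (!is.null(b)) {
      feats <- unlist(b$features)
      b <- rbind(lo = stats::setNames(as.numeric(unlist(b$lo)), feats),
                 hi = stats::setNames(as.numeric(unlist(b$hi)), feats))
    }
    tibble::tibble(
      template_id = tp$template_id, montage = tp$montage,
      channel = tp$channel, source_recording = tp$source_recording,
      onset_s = tp$onset_s, duration_s = tp$duration_s,
      waveform = list(as.numeric(unlist(tp$waveform))),
      true_count = as.integer(tp$true_count),
      false_count = as.integer(tp$false_count),
      classifier = list(clf), bounds = list(b)
    )
  })
  templates <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    template_id = character(), montage = character(), channel = character(),
    source_recording = character(), onset_s = numeric(), duration_s = numeric(),
    waveform = list(), true_count = integer(), false_count = integer(),
    classifier = list(), bounds = list()
  )
  meta <- lapply(payload$metadata, function(x) {
    if (is.list(x)) unlist(x) else x
  })
  new_template_db(templates, metadata = meta,
                  smoothing = isTRUE(payload$smoothing))
}
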