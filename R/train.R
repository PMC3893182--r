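# Training of the template database: scan the training recordings with
# every template, label supra-threshold detections against the annotations,
# fit a per-template linear SVM over the match features, record lifetime
# true/false counts, and learn property gates from the true detections.

#' Template reliability
#'
#' The lifetime fraction of true among all adjudicated detections,
#' `T / (T + F)`. With `smoothing = TRUE` the Laplace-smoothed form
#' `(T + 1) / (T + F + 2)` is used instead.
#'
#' @param true_count,false_count Nonnegative integer vectors.
#' @param smoothing Apply Laplace smoothing (default off).
#' @return Numeric vector of reliabilities in \[0, 1\].
#' @export
reliability <- function(true_count, false_count, smoothing = FALSE) {
  stopifnot(all(true_count >= 0), all(false_count >= 0))
  if (smoothing) {
    return((true_count + 1) / (true_count + false_count + 2))
  }
  total <- true_count + false_count
  if (any(total == 0)) {
    stop("reliability undefined for templates with zero adjudicated detections")
  }
  true_count / total
}

# least-squares linear max-margin classifier over the 4 match features,
# class-balanced; returns a self-contained parameter list
.fit_linear_classifier <- function(X, y, cost = 1) {
  n_true <- sum(y)
  n_false <- sum(!y)
  if (n_true == 0L) return(list(kind = "reject"))
  if (n_false == 0L) return(list(kind = "accept"))
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  yf <- factor(y, levels = c(FALSE, TRUE))
  n <- length(y)
  wts <- c("FALSE" = n / (2 * n_false), "TRUE" = n / (2 * n_true))
  model <- e1071::svm(Xs, yf, kernel = "linear", cost = cost,
                      scale = FALSE, class.weights = wts)
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  d <- drop(Xs %*% w) + b
  pred <- predict(model, Xs) == "TRUE"
  if (mean((d > 0) == pred) < 0.5) {
    w <- -w
    b <- -b
  }
  list(kind = "svm", w = w, b = b, center = center, scale = scale_)
}

# classifier decision score; positive = accept as IED
.classifier_score <- function(clf, X) {
  if (is.null(clf) || clf$kind == "reject") return(rep(-1, nrow(X)))
  if (clf$kind == "accept") return(rep(1, nrow(X)))
  Xs <- sweep(sweep(as.matrix(X), 2L, clf$center), 2L, clf$scale, "/")
  drop(Xs %*% clf$w) + clf$b
}

# [min, max] of true-detection features, each side widened by 10% of width
.feature_bounds <- function(X_true) {
  lo <- apply(X_true, 2L, min)
  hi <- apply(X_true, 2L, max)
  pad <- 0.1 * (hi - lo)
  zero <- pad == 0
  pad[zero] <- 0.1 * abs(lo[zero]) + 1e-9
  rbind(lo = lo - pad, hi = hi + pad)
}

.within_bounds <- function(bounds, X) {
  if (is.null(bounds)) return(rep(FALSE, nrow(X)))
  X <- as.matrix(X)
  ok <- rep(TRUE, nrow(X))
  for (j in colnames(bounds)) {
    ok <- ok & X[, j] >= bounds["lo", j] & X[, j] <= bounds["hi", j]
  }
  ok
}

# does candidate interval [start_s, end_s) overlap an ied annotation whose
# electrode participates in the scanned channel?
.truth_overlap <- function(ann, rec_id, channel, montage, start_s, end_s) {
  if (!nrow(ann)) return(FALSE)
  electrodes <- channel_electrodes(channel, montage)
  hit <- ann$recording_id == rec_id &
    ann$channel %in% electrodes &
    ann$onset_s < end_s &
    (ann$onset_s + ann$duration_s) > start_s
  any(hit)
}

# scan every channel of all same-montage recordings with one template;
# returns features + truth labels for all supra-threshold candidates
.scan_template <- function(waveform, derived, ffts, ann, montage, threshold) {
  m <- length(waveform)
  fs <- 100
  out <- list()
  for (rid in names(derived)) {
    rec <- derived[[rid]]
    traces <- .trace_all_channels(ffts[[rid]], waveform)
    for (ci in seq_along(rec$channel_labels)) {
      ch <- rec$channel_labels[ci]
      cands <- .find_candidates(traces[, ci], m, threshold)
      for (i in cands) {
        epoch <- rec$signal[ci, i:(i + m - 1L)]
        pre_from <- max(1L, i - fs)
        preceding <- if (i > 1L) rec$signal[ci, pre_from:(i - 1L)] else numeric()
        feats <- compute_match_features(epoch, preceding, waveform)
        start_s <- (i - 1L) / fs
        feats$truth <- .truth_overlap(ann, rid, ch, montage,
                                      start_s, start_s + m / fs)
        feats$recording_id <- rid
        feats$channel <- ch
        feats$start <- i - 1L
        out[[length(out) + 1L]] <- feats
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else NULL
}

#' Train the template database
#'
#' For each extracted template, scans every channel of every same-montage
#' training recording with the sliding correlation, collects epochs with
#' correlation above the detection threshold, labels each true or false by
#' overlap with the channel-level annotations, fits a class-balanced linear
#' SVM on the match features, stores the lifetime true/false counts, and
#' learns property bounds as the widened \[min, max\] of each feature over
#' the true detections.
#'
#' @param templates Template tibble from [extract_templates()].
#' @param recordings Preprocessed common-reference training recordings.
#' @param annotations Channel-level annotation tibble.
#' @param threshold Detection correlation threshold (default 0.85, strict).
#' @param cost SVM regularization constant.
#' @param config Montage table.
#' @return An `ied_template_db` object (untrained/undetected templates keep
#'   zero counts and are removed later by [prune_templates()]).
#' @export
train_templates <- function(templates, recordings, annotations,
                            threshold = 0.85, cost = 1,
                            config = montage_config()) {
  validate_annotations(annotations)
  ann <- dplyr::filter(annotations, .data$label == "ied", !is.na(.data$channel))
  recs <- stats::setNames(recordings,
                          vapply(recordings, `[[`, character(1), "recording_id"))
  n <- nrow(templates)
  true_count <- integer(n)
  false_count <- integer(n)
  classifier <- vector("list", n)
  bounds <- vector("list", n)
  for (mont in unique(templates$montage)) {
    derived <- lapply(recs, derive_montage, montage = mont, config = config)
    ffts <- lapply(derived, function(r) .channel_ffts(r$signal))
    idx <- which(templates$montage == mont)
    for (ti in idx) {
      det <- .scan_template(templates$waveform[[ti]], derived, ffts, ann,
                            mont, threshold)
      if (is.null(det)) {
        classifier[[ti]] <- list(kind = "reject")
        next
      }
      X <- as.matrix(det[, .FEATURE_NAMES])
      true_count[ti] <- sum(det$truth)
      false_count[ti] <- sum(!det$truth)
      classifier[[ti]] <- .fit_linear_classifier(X, det$truth, cost = cost)
      if (true_count[ti] > 0L) {
        bounds[[ti]] <- .feature_bounds(X[det$truth, , drop = FALSE])
      }
    }
  }
  tpl <- templates
  tpl$true_count <- true_count
  tpl$false_count <- false_count
  tpl$classifier <- classifier
  tpl$bounds <- bounds
  new_template_db(tpl, metadata = list(
    training_recordings = names(recs),
    threshold = threshold, cost = cost,
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC")
  ))
}

#' Construct a template database object
#'
#' @param templates Template tibble carrying counts, classifiers and bounds.
#' @param metadata Build metadata list.
#' @param smoothing Use Laplace-smoothed reliabilities.
#' @return An `ied_template_db`.
#' @export
new_template_db <- function(templates, metadata = list(), smoothing = FALSE) {
  stopifnot(!anyDuplicated(templates$template_id))
  structure(
    list(templates = templates, metadata = metadata,
         smoothing = smoothing, version = 1L),
    class = "ied_template_db"
  )
}

#' @export
print.ied_template_db <- function(x, ...) {
  cat(sprintf("<ied_template_db> %d templates (%s)\n",
              nrow(x$templates),
              paste(sprintf("%s: %d", names(table(x$templates$montage)),
                            table(x$templates$montage)), collapse = ", ")))
  invisible(x)
}

#' Discard uninformative templates
#'
#' Removes templates with zero detections, with only false detections, or
#' with fewer than `min_true` correct detections and no false detections.
#'
#' @param db An `ied_template_db` from [train_templates()].
#' @param min_true Minimum true-detection count for a false-free template to
#'   survive (default 2).
#' @return The pruned database; every survivor has `T + F >= 1`.
#' @export
prune_templates <- function(db, min_true = 2) {
  stopifnot(inherits(db, "ied_template_db"))
  keep <- with(db$templates,
    !(true_count + false_count == 0 |
        (true_count == 0 & false_count > 0) |
        (true_count > 0 & true_count < min_true & false_count == 0)))
  db$templates <- db$templates[keep, ]
  db$metadata$min_true <- min_true
  db
}

#' Template reliabilities of a database
#'
#' @param db An `ied_template_db` (pruned, so all counts are positive).
#' @return Named numeric vector of reliabilities, by `template_id`.
#' @export
db_reliabilities <- function(db) {
  stats::setNames(
    reliability(db$templates$true_count, db$templates$false_count,
                smoothing = db$smoothing),
    db$templates$template_id
  )
}

#' Apply true/false count increments to a database
#'
#' The global update for sustained learning: after a completed review, the
#' per-template deltas implied by the reviewer's confirmations and
#' rejections are added to the lifetime counts.
#'
#' @param db An `ied_template_db`.
#' @param deltas Tibble with columns `template_id`, `delta_true`,
#'   `delta_false`.
#' @return The updated database.
#' @export
apply_count_deltas <- function(db, deltas) {
  stopifnot(inherits(db, "ied_template_db"))
  if (!nrow(deltas)) return(db)
  unknown <- setdiff(deltas$template_id, db$templates$template_id)
  if (length(unknown)) {
    stop("unknown template ids: ", paste(unknown, collapse = ", "))
  }
  i <- match(deltas$template_id, db$templates$template_id)
  db$templates$true_count[i] <- db$templates$true_count[i] + deltas$delta_true
  db$templates$false_count[i] <- db$templates$false_count[i] + deltas$delta_false
  stopifnot(all(db$templates$true_count >= 0),
            all(db$templates$false_count >= 0))
  db
}

#' Summaries of a template database
#'
#' `tidy()` returns one row per template (id, montage, channel, duration,
#' counts, reliability); `glance()` returns one-row totals.
#'
#' @param x An `ied_template_db`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ied_template_db <- function(x, ...) {
  t <- x$templates
  total <- t$true_count + t$false_count
  rel <- ifelse(total > 0,
                ifelse(rep(x$smoothing, nrow(t)),
                       (t$true_count + 1) / (total + 2),
                       t$true_count / pmax(total, 1L)),
                NA_real_)
  tibble::tibble(
    template_id = t$template_id, montage = t$montage, channel = t$channel,
    source_recording = t$source_recording, duration_s = t$duration_s,
    true_count = t$true_count, false_count = t$false_count,
    reliability = rel
  )
}

#' @rdname tidy.ied_template_db
#' @export
glance.ied_template_db <- function(x, ...) {
  td <- tidy.ied_template_db(x)
  tibble::tibble(
    n_templates = nrow(td),
    n_montages = length(unique(td$montage)),
    total_true = sum(td$true_count),
    total_false = sum(td$false_count),
    mean_reliability = mean(td$reliability)
  )
}
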