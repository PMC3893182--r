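# Iterative certainty-ranked review. Batches of the most certain pending
# groups are presented; confirm/reject feedback updates session-local
# effective template reliabilities and re-ranks the remaining pool. The
# persistent database changes only at finalize, so an abandoned review
# leaves it untouched.

#' Start a review session
#'
#' @param groups Grouped-nomination tibble (from [group_nominations()]),
#'   all statuses `"pending"`, from one recording.
#' @param db The `ied_template_db` used for detection; its counts seed the
#'   session-local effective reliabilities.
#' @param batch_size Nominations presented per iteration (default 10).
#' @param aggregator Certainty aggregator name.
#' @return An `ied_review_session`.
#' @export
start_review <- function(groups, db, batch_size = 10,
                         aggregator = "noisy_or") {
  stopifnot(inherits(db, "ied_template_db"), batch_size >= 1)
  base <- db$templates[, c("template_id", "true_count", "false_count")]
  pool <- group_certainty(groups, rel = db_reliabilities(db),
                          aggregator = aggregator)
  structure(
    list(
      pool = pool,
      base_counts = base,
      deltas = tibble::tibble(template_id = base$template_id,
                              delta_true = 0L, delta_false = 0L),
      log = tibble::tibble(iteration = integer(), group_id = character(),
                           certainty = numeric(), outcome = character()),
      iteration = 0L,
      batch_size = as.integer(batch_size),
      aggregator = aggregator,
      smoothing = db$smoothing,
      finalized = FALSE
    ),
    class = "ied_review_session"
  )
}

#' @export
print.ied_review_session <- function(x, ...) {
  cat(sprintf(
    "<ied_review_session> iteration %d; %d pending / %d total groups; %s\n",
    x$iteration, sum(x$pool$status == "pending"), nrow(x$pool),
    if (session_complete(x)) "complete" else "in progress"))
  invisible(x)
}

#' Is the review complete?
#' @param session An `ied_review_session`.
#' @return TRUE when no pending groups remain.
#' @export
session_complete <- function(session) {
  !any(session$pool$status == "pending")
}

#' Iterations available at the current batch size
#' @param session An `ied_review_session`.
#' @return `ceiling(pending / batch_size)`.
#' @export
session_iterations_left <- function(session) {
  ceiling(sum(session$pool$status == "pending") / session$batch_size)
}

# current session-local effective reliabilities
.effective_reliabilities <- function(session) {
  b <- session$base_counts
  d <- session$deltas
  stats::setNames(
    reliability(b$true_count + d$delta_true,
                b$false_count + d$delta_false,
                smoothing = session$smoothing),
    b$template_id
  )
}

#' Next batch of groups to present
#'
#' The pending groups with highest certainty, ties broken by earlier onset
#' then smaller group id, returned in descending certainty. Empty when the
#' session is complete.
#'
#' @param session An `ied_review_session`.
#' @return Tibble of at most `batch_size` groups.
#' @export
next_batch <- function(session) {
  pending <- dplyr::filter(session$pool, .data$status == "pending")
  if (!nrow(pending)) return(pending)
  pending <- dplyr::arrange(pending, dplyr::desc(.data$certainty),
                            .data$onset_s, .data$group_id)
  utils::head(pending, session$batch_size)
}

#' Submit reviewer outcomes for the presented batch
#'
#' Every group of the current batch must receive exactly one outcome
#' (`"confirm"`, `"reject"` or `"unsure"`). Confirmations add one true
#' prediction per member nomination to that nomination's template;
#' rejections add one false prediction per member; `"unsure"` adds nothing.
#' Effective reliabilities and the certainties of all still-pending groups
#' are then recomputed and the iteration counter advances.
#'
#' @param session An `ied_review_session`.
#' @param outcomes Tibble with columns `group_id`, `outcome`, or a named
#'   character vector (names = group ids).
#' @param batch_ids Group ids that were presented. Defaults to the
#'   certainty-ranked [next_batch()]; pass explicitly when presenting under
#'   a different policy.
#' @return The updated session.
#' @export
submit_feedback <- function(session, outcomes, batch_ids = NULL) {
  stopifnot(inherits(session, "ied_review_session"))
  if (!is.data.frame(outcomes)) {
    outcomes <- tibble::tibble(group_id = names(outcomes),
                               outcome = unname(outcomes))
  }
  stopifnot(all(outcomes$outcome %in% c("confirm", "reject", "unsure")))
  if (is.null(batch_ids)) batch_ids <- next_batch(session)$group_id
  pending_ids <- session$pool$group_id[session$pool$status == "pending"]
  if (length(bad <- setdiff(batch_ids, pending_ids))) {
    stop("groups not pending (already presented?): ",
         paste(bad, collapse = ", "))
  }
  extra <- setdiff(outcomes$group_id, batch_ids)
  if (length(extra)) {
    stop("outcome given for group(s) not in the presented batch: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(batch_ids, outcomes$group_id)
  if (length(missing)) {
    stop("no outcome for presented group(s): ",
         paste(missing, collapse = ", "))
  }
  status_for <- c(confirm = "confirmed", reject = "rejected",
                  unsure = "unsure")
  it <- session$iteration + 1L
  for (i in seq_len(nrow(outcomes))) {
    gid <- outcomes$group_id[i]
    oc <- outcomes$outcome[i]
    gi <- match(gid, session$pool$group_id)
    session$pool$status[gi] <- status_for[[oc]]
    session$log <- dplyr::bind_rows(session$log, tibble::tibble(
      iteration = it, group_id = gid,
      certainty = session$pool$certainty[gi], outcome = oc))
    if (oc == "unsure") next
    mem <- session$pool$members[[gi]]
    cnt <- table(mem$template_id)
    di <- match(names(cnt), session$deltas$template_id)
    if (anyNA(di)) {
      stop("member template(s) unknown to the session: ",
           paste(names(cnt)[is.na(di)], collapse = ", "))
    }
    if (oc == "confirm") {
      session$deltas$delta_true[di] <- session$deltas$delta_true[di] +
        as.integer(cnt)
    } else {
      session$deltas$delta_false[di] <- session$deltas$delta_false[di] +
        as.integer(cnt)
    }
  }
  rel <- .effective_reliabilities(session)
  pend <- session$pool$status == "pending"
  if (any(pend)) {
    session$pool$certainty[pend] <- vapply(
      session$pool$members[pend], function(mem) {
        certainty_value(mem$correlation, unname(rel[mem$template_id]),
                        session$aggregator)
      }, numeric(1))
  }
  session$iteration <- it
  session
}

#' Finalize a review: export confirmations, update the database
#'
#' Confirmed groups become `"ied"` annotations (onset, duration, channels);
#' the accumulated per-template deltas are applied to the database — the
#' global update for sustained learning. Finalizing an already-finalized
#' session applies empty deltas, so the call is idempotent.
#'
#' @param session An `ied_review_session`.
#' @param db The `ied_template_db` to update.
#' @param recording_id Recording id stamped on the exported annotations.
#' @return List with `annotations`, `db` (updated) and `session` (marked
#'   finalized, deltas cleared).
#' @export
finalize_review <- function(session, db, recording_id = "recording") {
  stopifnot(inherits(session, "ied_review_session"),
            inherits(db, "ied_template_db"))
  confirmed <- dplyr::filter(session$pool, .data$status == "confirmed")
  ann <- if (nrow(confirmed)) {
    annotation_table(
      recording_id = recording_id,
      channel = vapply(confirmed$channels, paste, character(1),
                       collapse = ";"),
      onset_s = confirmed$onset_s,
      duration_s = confirmed$duration_s,
      label = "ied"
    )
  } else annotation_table()
  deltas <- if (session$finalized) {
    session$deltas[0, ]
  } else {
    dplyr::filter(session$deltas,
                  .data$delta_true > 0 | .data$delta_false > 0)
  }
  db <- apply_count_deltas(db, deltas)
  session$finalized <- TRUE
  session$deltas$delta_true <- 0L
  session$deltas$delta_false <- 0L
  list(annotations = ann, db = db, session = session)
}

#' Tidy / glance a review session
#'
#' `tidy()` returns the feedback log; `glance()` one-row session totals.
#'
#' @param x An `ied_review_session`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ied_review_session <- function(x, ...) x$log

#' @rdname tidy.ied_review_session
#' @export
glance.ied_review_session <- function(x, ...) {
  tibble::tibble(
    iterations = x$iteration,
    n_groups = nrow(x$pool),
    n_pending = sum(x$pool$status == "pending"),
    n_confirmed = sum(x$pool$status == "confirmed"),
    n_rejected = sum(x$pool$status == "rejected"),
    n_unsure = sum(x$pool$status == "unsure"),
    finalized = x$finalized
  )
}

#' Write the feedback log as JSON lines
#'
#' One JSON record per presentation: iteration, group id, certainty at
#' presentation time, outcome.
#'
#' @param session An `ied_review_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(session$log))) {
    writeLines(jsonlite::toJSON(as.list(session$log[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
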