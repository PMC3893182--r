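# Simulated reviewer: confirms a presented group iff its interval overlaps
# a ground-truth event. Used to evaluate how fast the certainty-ranked
# presentation surfaces the true events, against a random-order baseline.

.overlaps_any <- function(onset, duration, truth, tolerance_s = 0) {
  if (!nrow(truth)) return(rep(FALSE, length(onset)))
  vapply(seq_along(onset), function(i) {
    any(truth$onset_s - tolerance_s < onset[i] + duration[i] &
          truth$onset_s + truth$duration_s + tolerance_s > onset[i])
  }, logical(1))
}

# truth events overlapped by at least one of the given intervals
.truth_hit <- function(truth, onset, duration) {
  if (!nrow(truth)) return(logical(0))
  vapply(seq_len(nrow(truth)), function(i) {
    any(onset < truth$onset_s[i] + truth$duration_s[i] &
          onset + duration > truth$onset_s[i])
  }, logical(1))
}

#' Run a simulated review against ground truth
#'
#' An automatic reviewer works through the session: each presented group is
#' confirmed when its interval overlaps a ground-truth event (no channel
#' information is used, mirroring onset/duration-only evaluation marks) and
#' rejected otherwise. Under `policy = "certainty"` batches come from
#' [next_batch()]; under `policy = "random"` each batch is a uniformly
#' random draw of pending groups (the no-ranking baseline), seeded.
#'
#' @param session A fresh `ied_review_session`.
#' @param truth Ground-truth tibble with `onset_s`, `duration_s` for the
#'   session's recording.
#' @param max_iterations Maximum review iterations (default 15).
#' @param policy `"certainty"` or `"random"`.
#' @param seed Seed for the random policy.
#' @param tolerance_s Extra slack added around truth intervals.
#' @return List with `session` (after feedback) and `curve`, a tibble of
#'   class `ied_recall_curve` with one row per iteration: cumulative
#'   presented and confirmed groups, cumulative distinct truth events
#'   confirmed, and `recall` relative to the detectable (nominated) truth
#'   events.
#' @export
simulate_review <- function(session, truth, max_iterations = 15,
                            policy = c("certainty", "random"), seed = 1,
                            tolerance_s = 0) {
  policy <- match.arg(policy)
  stopifnot(inherits(session, "ied_review_session"))
  detectable <- sum(.truth_hit(truth, session$pool$onset_s,
                               session$pool$duration_s))
  run <- function() {
    rows <- list()
    for (it in seq_len(max_iterations)) {
      if (session_complete(session)) break
      batch <- if (policy == "certainty") {
        next_batch(session)
      } else {
        pending <- dplyr::filter(session$pool, .data$status == "pending")
        pending[sample.int(nrow(pending),
                           min(session$batch_size, nrow(pending))), ]
      }
      is_true <- .overlaps_any(batch$onset_s, batch$duration_s, truth,
                               tolerance_s)
      outcomes <- tibble::tibble(
        group_id = batch$group_id,
        outcome = ifelse(is_true, "confirm", "reject")
      )
      session <<- submit_feedback(session, outcomes,
                                  batch_ids = batch$group_id)
      confirmed <- dplyr::filter(session$pool, .data$status == "confirmed")
      hit <- .truth_hit(truth, confirmed$onset_s, confirmed$duration_s)
      rows[[it]] <- tibble::tibble(
        iteration = it,
        n_presented = sum(session$pool$status != "pending"),
        n_confirmed_groups = nrow(confirmed),
        truth_confirmed = sum(hit),
        truth_detectable = detectable,
        truth_total = nrow(truth),
        recall = if (detectable > 0) sum(hit) / detectable else NA_real_
      )
    }
    dplyr::bind_rows(rows)
  }
  curve <- if (policy == "random") .with_seed(seed, run()) else run()
  class(curve) <- c("ied_recall_curve", class(curve))
  list(session = session, curve = curve)
}

#' Iterations needed to reach a recall level
#'
#' @param curve An `ied_recall_curve`.
#' @param level Target recall fraction (default 0.8).
#' @return Smallest iteration whose recall is >= `level`, or `Inf`.
#' @export
iterations_to_recall <- function(curve, level = 0.8) {
  hit <- which(curve$recall >= level)
  if (length(hit)) curve$iteration[hit[1]] else Inf
}

#' Plot a recall curve
#'
#' @param object An `ied_recall_curve` (or several row-bound together with
#'   a `label` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ied_recall_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(df$label)) df$label <- "review"
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$recall,
                                   colour = .data$label)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "review iteration",
                  y = "detectable truth events confirmed",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a recall curve as CSV
#'
#' @param curve An `ied_recall_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recall_curve <- function(curve, path) {
  utils::write.csv(tibble::as_tibble(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
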