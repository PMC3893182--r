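# Review loop: batching, tie-breaking, delta bookkeeping, finalize
# conservation and the feedback-driven re-ranking.

.mk_member <- function(id, corr = 0.9) {
  tibble::tibble(
    recording_id = "fix", template_id = id,
    montage = "common_reference", channel = "C3",
    start = 0L, length = 50L, start_s = 0, duration_s = 0.5,
    correlation = corr, matching_variance = 0,
    amplitude_difference = 0, background_ratio = 1, reliability = NA_real_)
}

.simple_session <- function(n_groups = 25, batch_size = 10) {
  db <- make_count_db(c("a", "b", "c"), c(4L, 3L, 2L), c(1L, 1L, 2L))
  groups <- dplyr::bind_rows(lapply(seq_len(n_groups), function(i) {
    make_group(sprintf("g%02d", i), onset_s = i * 2, duration_s = 0.5,
               members = .mk_member(c("a", "b", "c")[1 + i %% 3],
                                    corr = 0.5 + 0.02 * i))
  }))
  list(session = start_review(groups, db, batch_size = batch_size), db = db)
}

test_that("session setup reports iterations and completion correctly", {
  s <- .simple_session(25)$session
  expect_equal(session_iterations_left(s), 3) # ceil(25/10)
  expect_false(session_complete(s))
  expect_equal(nrow(next_batch(s)), 10)

  empty <- start_review(make_group("g", 1, 0.5, .mk_member("a"))[0, ],
                        make_count_db("a", 1L, 0L))
  expect_true(session_complete(empty))
  expect_equal(nrow(next_batch(empty)), 0)

  small <- .simple_session(4, batch_size = 5)$session
  expect_equal(nrow(next_batch(small)), 4)
})

test_that("batches are certainty-ranked with deterministic tie-breaking", {
  db <- make_count_db("a", 3L, 1L)
  groups <- dplyr::bind_rows(
    make_group("g-late", onset_s = 9, duration_s = 0.5, .mk_member("a", 0.9)),
    make_group("g-early", onset_s = 2, duration_s = 0.5, .mk_member("a", 0.9)),
    make_group("g-top", onset_s = 5, duration_s = 0.5, .mk_member("a", 0.99)))
  s <- start_review(groups, db, batch_size = 2)
  batch <- next_batch(s)
  expect_equal(batch$group_id, c("g-top", "g-early")) # tie -> earlier onset
  expect_true(all(diff(batch$certainty) <= 0))
})

test_that("feedback bookkeeping counts one delta per member nomination", {
  db <- make_count_db(c("a", "b", "c"), c(4L, 3L, 2L), c(1L, 1L, 2L))
  g1 <- make_group("g1", 1, 0.5,
                   dplyr::bind_rows(.mk_member("a"), .mk_member("b"),
                                    .mk_member("c")))
  g2 <- make_group("g2", 5, 0.5,
                   dplyr::bind_rows(.mk_member("a"), .mk_member("a")))
  s <- start_review(dplyr::bind_rows(g1, g2), db, batch_size = 2)
  s <- submit_feedback(s, c(g1 = "confirm", g2 = "reject"))

  d <- s$deltas
  expect_equal(d$delta_true[d$template_id %in% c("a", "b", "c")],
               c(1L, 1L, 1L)) # confirm: +1 true per member
  expect_equal(d$delta_false[d$template_id == "a"], 2L) # two members, same tpl
  expect_equal(s$iteration, 1L)
  expect_true(session_complete(s))
})

test_that("outcomes must exactly cover the presented batch", {
  s <- .simple_session(15)$session
  batch <- next_batch(s)
  full <- stats::setNames(rep("unsure", 10), batch$group_id)
  expect_error(submit_feedback(s, full[-1]), "no outcome")
  wrong <- c(full, zz = "confirm")
  expect_error(submit_feedback(s, wrong), "not in the presented batch")
  s2 <- submit_feedback(s, full)
  expect_error(submit_feedback(s2, full, batch_ids = batch$group_id),
               "already presented")
})

test_that("unsure outcomes change no deltas and no certainties", {
  s <- .simple_session(15)$session
  before <- s$pool$certainty
  batch <- next_batch(s)
  s2 <- submit_feedback(s, stats::setNames(rep("unsure", 10),
                                           batch$group_id))
  expect_equal(sum(s2$deltas$delta_true), 0L)
  expect_equal(sum(s2$deltas$delta_false), 0L)
  expect_equal(s2$pool$certainty, before)
})

test_that("within-session updates never touch templates without feedback", {
  db <- make_count_db(c("a", "b"), c(4L, 4L), c(1L, 1L))
  ga <- make_group("ga", 1, 0.5, .mk_member("a"))
  gb1 <- make_group("gb1", 5, 0.5, .mk_member("b"))
  gb2 <- make_group("gb2", 9, 0.5, .mk_member("b"))
  s <- start_review(dplyr::bind_rows(ga, gb1, gb2), db, batch_size = 1)
  s <- submit_feedback(s, c(gb1 = "reject"), batch_ids = "gb1")
  # template a untouched: its group's certainty is unchanged
  ia <- match("ga", s$pool$group_id)
  expect_equal(s$pool$certainty[ia], certainty_value(0.9, 0.8))
  # template b weakened: remaining b-group certainty dropped
  ib <- match("gb2", s$pool$group_id)
  expect_lt(s$pool$certainty[ib], certainty_value(0.9, 0.8))
})

test_that("finalize conserves counts, exports confirmations, idempotent", {
  fix <- .simple_session(12)
  s <- fix$session
  batch <- next_batch(s)
  out <- stats::setNames(rep(c("confirm", "reject"), 5), batch$group_id)
  s <- submit_feedback(s, out)

  fin <- finalize_review(s, fix$db, recording_id = "fix")
  # counts = base + per-detection deltas implied by the log
  log_deltas <- dplyr::count(
    dplyr::mutate(
      dplyr::filter(s$log, outcome != "unsure"),
      template_id = vapply(group_id, function(g) {
        s$pool$members[[match(g, s$pool$group_id)]]$template_id[1]
      }, character(1))),
    template_id, outcome)
  for (i in seq_len(nrow(log_deltas))) {
    row <- log_deltas[i, ]
    base <- fix$db$templates
    upd <- fin$db$templates
    j <- match(row$template_id, base$template_id)
    if (row$outcome == "confirm") {
      expect_equal(upd$true_count[j], base$true_count[j] + row$n)
    } else {
      expect_equal(upd$false_count[j], base$false_count[j] + row$n)
    }
  }
  expect_equal(nrow(fin$annotations), 5)
  expect_true(all(fin$annotations$label == "ied"))

  # second finalize applies nothing further
  fin2 <- finalize_review(fin$session, fin$db)
  expect_identical(fin2$db$templates$true_count,
                   fin$db$templates$true_count)

  # zero confirmations: empty annotations, counts unchanged
  s0 <- .simple_session(3)$session
  b0 <- next_batch(s0)
  s0 <- submit_feedback(s0, stats::setNames(rep("unsure", nrow(b0)),
                                            b0$group_id))
  fin0 <- finalize_review(s0, fix$db)
  expect_equal(nrow(fin0$annotations), 0)
  expect_identical(fin0$db$templates$true_count,
                   fix$db$templates$true_count)
})

test_that("rejecting a template set demotes its remaining groups", {
  # templates in A only ever hit true events; B only false ones
  db <- make_count_db(c("a1", "a2", "b1", "b2"),
                      c(6L, 6L, 5L, 5L), c(2L, 2L, 1L, 1L))
  mk <- function(id, tpl, onset) make_group(id, onset, 0.5,
                                            .mk_member(tpl, corr = 0.95))
  groups <- dplyr::bind_rows(
    mk("b-g1", "b1", 1), mk("b-g2", "b2", 3), mk("b-g3", "b1", 5),
    mk("b-g4", "b2", 7),
    mk("a-g1", "a1", 9), mk("a-g2", "a2", 11), mk("a-g3", "a1", 13))
  s <- start_review(groups, db, batch_size = 2)
  rank_of <- function(pool, ids) {
    pend <- pool[pool$status == "pending", ]
    ord <- pend$group_id[order(-pend$certainty, pend$onset_s, pend$group_id)]
    match(ids, ord)
  }
  remaining_b <- c("b-g3", "b-g4")
  # B starts more reliable (5/6 > 6/8): its groups outrank A's
  expect_true(all(rank_of(s$pool, remaining_b) <= 4))
  control <- s # no-update control keeps the initial certainties
  s <- submit_feedback(s, c(`b-g1` = "reject", `b-g2` = "reject"),
                       batch_ids = c("b-g1", "b-g2"))
  control$pool$status[control$pool$group_id %in% c("b-g1", "b-g2")] <-
    "rejected"
  # mean certainty rank of the remaining B groups strictly worsens
  expect_gt(mean(rank_of(s$pool, remaining_b)),
            mean(rank_of(control$pool, remaining_b)))
  # and they now sit below every A group
  expect_true(min(rank_of(s$pool, remaining_b)) >
                max(rank_of(s$pool, c("a-g1", "a-g2", "a-g3"))))
})

test_that("the simulated reviewer produces monotone recall curves", {
  fix <- .simple_session(12)
  truth <- tibble::tibble(onset_s = c(4, 16), duration_s = c(0.6, 0.6))
  sim <- simulate_review(fix$session, truth, max_iterations = 5)
  expect_true(all(diff(sim$curve$truth_confirmed) >= 0))
  expect_true(all(diff(sim$curve$n_presented) >= 0))

  # empty truth: everything rejected, zero recall
  sim0 <- simulate_review(.simple_session(12)$session,
                          truth[0, ], max_iterations = 5)
  expect_true(all(sim0$curve$truth_confirmed == 0))
  expect_true(all(sim0$session$pool$status == "rejected"))

  # a truth event overlapping the top-certainty groups is found at once
  sim1 <- simulate_review(fix$session, tibble::tibble(
    onset_s = 2 * (1:12), duration_s = 0.5), max_iterations = 2)
  expect_gt(sim1$curve$truth_confirmed[1], 0)
})

test_that("session tidiers and the JSON-lines log agree", {
  fix <- .simple_session(12)
  s <- fix$session
  b <- next_batch(s)
  s <- submit_feedback(s, stats::setNames(
    rep(c("confirm", "unsure"), 5), b$group_id))
  expect_equal(nrow(tidy(s)), 10)
  g <- glance(s)
  expect_equal(g$n_confirmed, 5)
  expect_equal(g$n_unsure, 5)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(s, path)
  lines <- readLines(path)
  expect_length(lines, 10)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$iteration, 1)
  expect_true(rec$outcome %in% c("confirm", "unsure"))
})
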