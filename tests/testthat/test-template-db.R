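# Template extraction, match features, training counts, pruning rules,
# reliability bookkeeping and database persistence.

test_that("extraction yields one template per (event, channel, montage) mark", {
  bg <- generate_background(60, seed = 31)
  ann <- annotation_table(
    recording_id = rep(bg$recording_id, 6),
    channel = rep(c("F3", "C3", "Cz"), 2),
    onset_s = rep(c(10, 30), each = 3),
    duration_s = 0.5
  )
  tpls <- extract_templates(list(bg), ann, montages = "common_reference")
  expect_equal(nrow(tpls), 6)

  # waveform is the recording slice, verbatim
  t1 <- tpls[1, ]
  i0 <- round(t1$onset_s * 100) + 1
  expect_equal(t1$waveform[[1]],
               as.numeric(bg$signal[t1$channel, i0:(i0 + 49)]))

  # out-of-range duration and out-of-recording epochs are skipped with reasons
  bad <- annotation_table(
    recording_id = rep(bg$recording_id, 2), channel = "F3",
    onset_s = c(5, 59.9), duration_s = c(0.9, 0.5))
  skipped <- extract_templates(list(bg), bad, montages = "common_reference")
  expect_equal(nrow(skipped), 0)
  expect_length(attr(skipped, "skipped"), 2)
})

test_that("bipolar extraction covers every chain the electrode takes part in", {
  bg <- generate_background(30, seed = 32)
  ann <- annotation_table(recording_id = bg$recording_id, channel = "C3",
                          onset_s = 10, duration_s = 0.4)
  tpls <- extract_templates(list(bg), ann, montages = "bipolar")
  expect_setequal(tpls$channel, c("F3-C3", "C3-P3"))
})

test_that("match features satisfy their defining identities", {
  w <- make_spike_wave(spike_wave_params(duration = 0.4), 100)
  pre <- w[1:30]

  f_same <- compute_match_features(w, pre, w)
  expect_equal(f_same$correlation, 1)
  expect_equal(f_same$matching_variance, 0)
  expect_equal(f_same$amplitude_difference, 0)

  f_double <- compute_match_features(2 * w, pre, w)
  expect_equal(f_double$correlation, 1)
  expect_equal(f_double$matching_variance, 0, tolerance = 1e-9)
  expect_equal(f_double$amplitude_difference, diff(range(w)))

  # independent per-formula recomputation on a random epoch
  set.seed(12)
  e <- rnorm(length(w), sd = 40)
  f <- compute_match_features(e, pre, w)
  expect_equal(f$correlation, cor(e, w))
  gain <- cov(e, w) / var(w) # least-squares gain of template onto epoch
  resid <- (e - mean(e)) - gain * (w - mean(w))
  expect_equal(f$matching_variance, sum(resid^2) / (length(w) - 1))
  expect_equal(f$amplitude_difference,
               abs(diff(range(e)) - diff(range(w))))
  expect_equal(f$background_ratio,
               sqrt(mean(e^2)) / sqrt(mean(pre^2)))

  flat <- compute_match_features(rep(3, length(w)), pre, w)
  expect_equal(flat$correlation, 0)
  expect_true(flat$degenerate)
})

test_that("training counts match a brute-force scan at the same threshold", {
  ds <- tiny_dataset()
  recs <- ds$training$recordings
  ann <- ds$training$annotations
  tpls <- extract_templates(recs, ann, montages = "common_reference")
  db <- train_templates(tpls[1:4, ], recs, ann)

  for (ti in 1:4) {
    w <- db$templates$waveform[[ti]]
    m <- length(w)
    n_true <- 0L; n_false <- 0L
    for (rec in recs) {
      for (ch in rec$channel_labels) {
        tr <- brute_sliding_correlation(rec$signal[ch, ], w)
        cand <- iedreview:::.find_candidates(tr, m, 0.85)
        for (i in cand) {
          s0 <- (i - 1) / 100
          hit <- any(ann$recording_id == rec$recording_id &
                       ann$channel == ch &
                       ann$onset_s < s0 + m / 100 &
                       ann$onset_s + ann$duration_s > s0)
          if (hit) n_true <- n_true + 1L else n_false <- n_false + 1L
        }
      }
    }
    expect_equal(db$templates$true_count[ti], n_true)
    expect_equal(db$templates$false_count[ti], n_false)
  }
})

test_that("a template detects its own source event during training", {
  db <- tiny_db()
  expect_true(all(db$templates$true_count + db$templates$false_count >= 1))
  expect_gt(nrow(db$templates), 0)
})

test_that("pruning implements the three discard rules", {
  counts <- tibble::tibble(
    true_count = c(0L, 0L, 1L, 1L, 5L),
    false_count = c(0L, 5L, 0L, 1L, 0L)
  )
  db <- make_count_db(sprintf("p%d", 1:5), counts$true_count,
                      counts$false_count)
  kept <- prune_templates(db, min_true = 2)$templates
  expect_setequal(kept$template_id, c("p4", "p5")) # (1,1) and (5,0)
})

test_that("reliability is T/(T+F), bounded, monotone, and errors on 0/0", {
  expect_equal(reliability(3, 1), 0.75)
  expect_equal(reliability(5, 0), 1)
  for (k in c(1, 4, 9)) expect_equal(reliability(k, k), 0.5)
  expect_error(reliability(0, 0), "zero")
  expect_equal(reliability(0, 0, smoothing = TRUE), 0.5)

  # monotone: non-decreasing in T, non-increasing in F
  base <- reliability(3, 2)
  expect_gte(reliability(4, 2), base)
  expect_lte(reliability(3, 3), base)
})

test_that("count deltas are exact and compose additively", {
  db <- make_count_db(c("a", "b"), c(3L, 2L), c(1L, 2L))
  d1 <- tibble::tibble(template_id = "a", delta_true = 2L, delta_false = 0L)
  up <- apply_count_deltas(db, d1)
  expect_equal(up$templates$true_count, c(5L, 2L))
  expect_equal(unname(db_reliabilities(up)["a"]), 5 / 6)

  expect_identical(apply_count_deltas(db, d1[0, ]), db)

  d2 <- tibble::tibble(template_id = c("a", "b"),
                       delta_true = c(1L, 0L), delta_false = c(0L, 3L))
  seq_applied <- apply_count_deltas(apply_count_deltas(db, d1), d2)
  combined <- apply_count_deltas(db, tibble::tibble(
    template_id = c("a", "b"), delta_true = c(3L, 0L),
    delta_false = c(0L, 3L)))
  expect_identical(seq_applied$templates, combined$templates)

  expect_error(apply_count_deltas(db, tibble::tibble(
    template_id = "zz", delta_true = 1L, delta_false = 0L)), "zz")
})

test_that("database persistence round-trips every field", {
  db <- tiny_db()
  path <- withr::local_tempfile(fileext = ".json")
  save_template_db(db, path)
  back <- load_template_db(path)
  expect_equal(back$templates$template_id, db$templates$template_id)
  expect_equal(back$templates$true_count, db$templates$true_count)
  expect_equal(back$templates$false_count, db$templates$false_count)
  for (i in seq_len(nrow(db$templates))) {
    expect_equal(back$templates$waveform[[i]], db$templates$waveform[[i]])
    expect_equal(back$templates$bounds[[i]], db$templates$bounds[[i]])
    clf_a <- db$templates$classifier[[i]]
    clf_b <- back$templates$classifier[[i]]
    expect_equal(clf_b$kind, clf_a$kind)
    if (identical(clf_a$kind, "svm")) {
      expect_equal(as.numeric(clf_b$w), as.numeric(clf_a$w))
      expect_equal(clf_b$b, clf_a$b)
    }
  }

  # count updates persist through a save/load cycle
  up <- apply_count_deltas(db, tibble::tibble(
    template_id = db$templates$template_id[1],
    delta_true = 3L, delta_false = 1L))
  save_template_db(up, path)
  expect_equal(load_template_db(path)$templates$true_count[1],
               db$templates$true_count[1] + 3L)

  writeLines("{\"format\": \"something-else\"}", path)
  expect_error(load_template_db(path), "format")
  writeLines("not json {", path)
  expect_error(load_template_db(path), "corrupt")
})
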