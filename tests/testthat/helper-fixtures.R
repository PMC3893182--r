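# Shared fixtures, memoized so expensive pipelines run once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small dataset exercising the whole pipeline quickly
tiny_dataset <- function() {
  memo("tiny_dataset", make_dataset(
    dataset_spec(n_train = 2, n_eval = 1, duration_s = 120, n_families = 2),
    seed = 42
  ))
}

tiny_db <- function() {
  memo("tiny_db", {
    ds <- tiny_dataset()
    tpls <- extract_templates(ds$training$recordings, ds$training$annotations)
    prune_templates(train_templates(tpls, ds$training$recordings,
                                    ds$training$annotations))
  })
}

tiny_nominations <- function() {
  memo("tiny_nominations", {
    detect_ieds(tiny_dataset()$evaluation$recordings[[1]], tiny_db())
  })
}

# straight-line per-window Pearson oracle, independent of the FFT path
brute_sliding_correlation <- function(signal, waveform) {
  m <- length(waveform)
  vapply(seq_len(length(signal) - m + 1L), function(i) {
    win <- signal[i:(i + m - 1L)]
    if (stats::sd(win) == 0 || stats::sd(waveform) == 0) return(0)
    stats::cor(win, waveform)
  }, numeric(1))
}

# hand-built nomination rows for grouping tests
make_nom <- function(channel, start, length, template_id,
                     correlation = 0.9, reliability = 0.8,
                     montage = "common_reference") {
  tibble::tibble(
    recording_id = "fix", template_id = template_id, montage = montage,
    channel = channel, start = as.integer(start),
    length = as.integer(length),
    start_s = start / 100, duration_s = length / 100,
    correlation = correlation, matching_variance = 0,
    amplitude_difference = 0, background_ratio = 1,
    reliability = reliability
  )
}

# hand-built group rows for review tests
make_group <- function(group_id, onset_s, duration_s, members) {
  tibble::tibble(
    group_id = group_id,
    start = as.integer(round(onset_s * 100)),
    end = as.integer(round((onset_s + duration_s) * 100)),
    onset_s = onset_s, duration_s = duration_s,
    channels = list(unique(members$channel)),
    n_members = nrow(members), members = list(members),
    status = "pending"
  )
}

# bare db with given counts; no classifiers or bounds needed for review
make_count_db <- function(ids, true_count, false_count) {
  n <- length(ids)
  new_template_db(tibble::tibble(
    template_id = ids, montage = "common_reference", channel = "C3",
    source_recording = "fix", onset_s = 0, duration_s = 0.5,
    waveform = replicate(n, numeric(50), simplify = FALSE),
    true_count = as.integer(true_count),
    false_count = as.integer(false_count),
    classifier = replicate(n, list(kind = "accept"), simplify = FALSE),
    bounds = replicate(n, NULL, simplify = FALSE)
  ))
}

# default-scale pipeline used by the acceptance checks (heavier; memoized)
default_pipeline <- function() {
  memo("default_pipeline", {
    ds <- make_dataset(dataset_spec(), seed = 101)
    tpls <- extract_templates(ds$training$recordings,
                              ds$training$annotations)
    db <- prune_templates(train_templates(tpls, ds$training$recordings,
                                          ds$training$annotations))
    noms <- lapply(ds$evaluation$recordings, detect_ieds, db = db)
    list(dataset = ds, templates = tpls, db = db, nominations = noms)
  })
}
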