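# EDF round trips, preprocessing chain, montage derivations, annotation I/O.

test_that("EDF write-read round trip preserves signals within quantization", {
  rec <- generate_background(20, seed = 11)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channel_labels, rec$channel_labels)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(ncol(back$signal), 20 * 100)
  # 16-bit quantization: error bounded by one digital step per channel
  step <- apply(abs(rec$signal), 1, max) * 1.0001 / 32767
  err <- apply(abs(back$signal - rec$signal), 1, max)
  expect_true(all(err <= step + 1e-9))
  expect_equal(back$recording_id, rec$recording_id)
})

test_that("EDF reader reports missing required electrodes by name", {
  rec <- generate_background(5, seed = 1)
  keep <- setdiff(rec$channel_labels, "Cz")
  partial <- eeg_recording(rec$signal[keep, ], keep, 100,
                           recording_id = "partial")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(partial, path)
  expect_error(read_edf(path), "Cz")
})

test_that("EDF reader rejects corrupt files", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF file at all", path)
  expect_error(read_edf(path), "EDF")
})

test_that("a 250 Hz recording keeps its native length through EDF", {
  n_s <- 12
  rec <- eeg_recording(
    matrix(rnorm(19 * n_s * 250), nrow = 19), electrodes_1020(), 250,
    recording_id = "native250")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_equal(ncol(read_edf(path)$signal), n_s * 250)
})

test_that("preprocess resamples to 100 Hz and band-limits", {
  n_s <- 20
  fs <- 256
  t <- seq_len(n_s * fs) / fs
  # mid-band tone + out-of-band tone + DC offset
  sig <- matrix(rep(50 * sin(2 * pi * 10 * t), 19), nrow = 19, byrow = TRUE)
  rec <- eeg_recording(sig + 100, electrodes_1020(), fs)
  out <- preprocess(rec)
  expect_equal(out$sample_rate, 100)
  expect_equal(ncol(out$signal), n_s * 100)
  # DC rejected by the 0.5 Hz high-pass edge
  expect_lt(abs(mean(out$signal[1, ])), 1)

  hf <- eeg_recording(
    matrix(rep(50 * sin(2 * pi * 45 * t), 19), nrow = 19, byrow = TRUE),
    electrodes_1020(), fs)
  hf_out <- preprocess(hf)
  mid <- (5 * 100):(15 * 100)
  atten <- 20 * log10(max(abs(hf_out$signal[1, mid])) / 50)
  expect_lt(atten, -20) # >= 20 dB down at 45 Hz
})

test_that("preprocess refuses sub-100 Hz input and is near-idempotent", {
  slow <- eeg_recording(matrix(rnorm(19 * 100), nrow = 19),
                        electrodes_1020(), 50)
  expect_error(preprocess(slow), "100 Hz")

  # mid-band content: a second pass changes almost nothing
  t <- seq_len(30 * 256) / 256
  sig <- 30 * sin(2 * pi * 9 * t) + 10 * sin(2 * pi * 4 * t + 1)
  rec <- eeg_recording(matrix(rep(sig, 19), nrow = 19, byrow = TRUE),
                       electrodes_1020(), 256)
  once <- preprocess(rec)
  twice <- preprocess(once)
  mid <- (5 * 100):(25 * 100)
  rel <- sqrt(mean((twice$signal[1, mid] - once$signal[1, mid])^2)) /
    sqrt(mean(once$signal[1, mid]^2))
  expect_lt(rel, 1e-2)
})

test_that("montage derivations follow the configured tables", {
  n <- 500
  same <- eeg_recording(matrix(rep(rnorm(n), 19), nrow = 19, byrow = TRUE),
                        electrodes_1020(), 100)
  bp <- derive_montage(same, "bipolar")
  expect_equal(max(abs(bp$signal)), 0)
  expect_equal(bp$channel_labels[1], "Fp1-F7")

  expect_identical(derive_montage(same, "common_reference"), same)
  expect_error(derive_montage(same, "average"), "unknown montage")

  # impulse on C3: C3 keeps it; each neighbour of C3 sees -1/(its own
  # neighbour count) of it
  cfg <- montage_config()
  imp <- matrix(0, 19, n, dimnames = list(electrodes_1020(), NULL))
  imp["C3", 250] <- 1
  rec <- eeg_recording(imp, electrodes_1020(), 100)
  lap <- derive_montage(rec, "laplacian")
  expect_equal(unname(lap$signal["C3", 250]), 1)
  for (nb in cfg$laplacian[["C3"]]) {
    expect_equal(unname(lap$signal[nb, 250]),
                 -1 / length(cfg$laplacian[[nb]]), info = nb)
  }
})

test_that("montage derivation is linear", {
  mk <- function(seed) generate_background(5, seed = seed)
  x <- mk(1); y <- mk(2)
  a <- 2.5; b <- -0.7
  combo <- eeg_recording(a * x$signal + b * y$signal, x$channel_labels, 100)
  for (m in c("bipolar", "laplacian")) {
    lhs <- derive_montage(combo, m)$signal
    rhs <- a * derive_montage(x, m)$signal + b * derive_montage(y, m)$signal
    expect_equal(lhs, rhs, tolerance = 1e-12, info = m)
  }
})

test_that("annotation CSV round trip is exact at millisecond precision", {
  ann <- annotation_table(
    recording_id = c("r1", "r1", "r2"),
    channel = c("C3", NA, "F4"),
    onset_s = c(1.234, 10.5, 0.001),
    duration_s = c(0.5, 0.25, 0.862),
    label = c("ied", "unsure", "ied")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_identical(read_annotations(path), ann)

  empty <- annotation_table()
  write_annotations(empty, path)
  expect_equal(length(readLines(path)), 1L) # header only
  write_annotations(ann, path)
  expect_equal(length(readLines(path)), 4L)
})
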