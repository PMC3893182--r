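# Seeded synthetic scalp EEG with injected spike-wave discharges.
# Stands in for clinical training/evaluation data: 19-channel 10-20
# background (1/f noise + posterior alpha, slowly varying gain) plus
# spike-and-slow-wave events with known ground truth.

# run expr under a temporary RNG state; restores the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# smooth unit-variance noise: white noise low-passed by a moving average
.slow_noise <- function(n, smooth_samples) {
  x <- stats::rnorm(n + 2L * smooth_samples)
  k <- rep(1 / smooth_samples, smooth_samples)
  s <- stats::filter(x, k, sides = 2L)
  s <- s[(smooth_samples + 1L):(smooth_samples + n)]
  s / stats::sd(s)
}

#' Generate synthetic EEG background
#'
#' Produces a 19-channel (by default) 100 Hz recording of 1/f-weighted noise
#' with a posterior-dominant 8-12 Hz rhythm on occipital/parietal channels
#' and a slow multiplicative gain modulation (so the background is
#' non-stationary in amplitude, as real EEG is). Channel RMS lies in roughly
#' 10-50 microvolts, larger posteriorly. Fully reproducible from `seed`.
#'
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed.
#' @param channel_labels Channel labels (default the 10-20 set).
#' @param sample_rate Output rate in Hz.
#' @param recording_id Identifier for the recording.
#' @return A common-reference `eeg_recording`.
#' @export
generate_background <- function(duration_s, seed,
                                channel_labels = electrodes_1020(),
                                sample_rate = 100,
                                recording_id = paste0("synth-", seed)) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * sample_rate)
  posterior <- c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")
  .with_seed(seed, {
    sig <- vapply(channel_labels, function(ch) {
      # 1/f-shaped noise via spectral weighting
      white <- stats::rnorm(n)
      spec <- stats::fft(white)
      f <- c(seq_len(ceiling(n / 2)), rev(seq_len(floor(n / 2)))) *
        sample_rate / n
      w <- 1 / sqrt(pmax(f, 1))
      w[1] <- 0 # no DC
      pink <- Re(stats::fft(spec * c(0, w[-1]), inverse = TRUE)) / n
      pink <- pink / stats::sd(pink)
      rms <- if (ch %in% posterior) stats::runif(1, 18, 30) else stats::runif(1, 10, 16)
      x <- pink * rms
      if (ch %in% posterior) {
        f0 <- stats::runif(1, 8, 12)
        env <- pmax(0.2, 1 + 0.6 * .slow_noise(n, 2L * sample_rate))
        alpha <- sin(2 * pi * f0 * seq_len(n) / sample_rate +
                       stats::runif(1, 0, 2 * pi))
        x <- x + stats::runif(1, 10, 20) * env * alpha
      }
      # slow amplitude non-stationarity (~0.1 Hz)
      gain <- exp(0.25 * .slow_noise(n, 5L * sample_rate))
      x * gain
    }, numeric(n))
  })
  eeg_recording(t(sig), channel_labels, sample_rate,
                montage = "common_reference", recording_id = recording_id)
}

#' Spike-wave event family parameters
#'
#' Describes one family of spike-and-slow-wave discharges: a sharp biphasic
#' transient (20-70 ms) followed by a slow wave filling the remaining
#' duration. Durations are constrained to the template range of
#' 0.212-0.860 s. `focus_channels` carry the event at full amplitude;
#' their 10-20 neighbours receive it scaled by `spread_attenuation`.
#'
#' @param duration Event duration in seconds, within \[0.212, 0.860\].
#' @param spike_amplitude Peak absolute amplitude of the transient, microvolts.
#' @param wave_amplitude Slow-wave amplitude, microvolts.
#' @param polarity `+1` or `-1`.
#' @param asymmetry Shape exponent (> 0) skewing the slow wave; 1 = symmetric.
#' @param focus_channels Electrode labels carrying the event at full gain.
#' @param spread_attenuation Gain in (0, 1] applied on neighbour channels.
#' @param spike_width Width of the sharp transient in seconds (0.02-0.07).
#' @param family_id Identifier string.
#' @return A `spike_wave_params` list.
#' @export
spike_wave_params <- function(duration = 0.5, spike_amplitude = 120,
                              wave_amplitude = 60, polarity = 1,
                              asymmetry = 1,
                              focus_channels = c("F3", "C3"),
                              spread_attenuation = 0.4,
                              spike_width = 0.05,
                              family_id = "family-1") {
  stopifnot(
    duration >= 0.212, duration <= 0.860,
    spike_amplitude > 0, wave_amplitude > 0,
    polarity %in% c(-1, 1), asymmetry > 0,
    length(focus_channels) >= 1,
    spread_attenuation > 0, spread_attenuation <= 1,
    spike_width >= 0.02, spike_width <= 0.07
  )
  structure(
    list(duration = duration, spike_amplitude = spike_amplitude,
         wave_amplitude = wave_amplitude, polarity = polarity,
         asymmetry = asymmetry, focus_channels = focus_channels,
         spread_attenuation = spread_attenuation, spike_width = spike_width,
         family_id = family_id),
    class = "spike_wave_params"
  )
}

#' Build a spike-wave prototype waveform
#'
#' Deterministic single-channel prototype: a difference-of-Gaussians sharp
#' transient over the first `spike_width` seconds, then a (possibly skewed)
#' half-sine slow wave over the rest of the duration. The waveform is scaled
#' so its peak absolute amplitude equals `spike_amplitude`, then multiplied
#' by `polarity`.
#'
#' @param params A [spike_wave_params()] object.
#' @param sample_rate Samples per second.
#' @return Numeric vector of length `round(duration * sample_rate)`.
#' @export
make_spike_wave <- function(params, sample_rate = 100) {
  if (!inherits(params, "spike_wave_params")) {
    params <- do.call(spike_wave_params, params)
  }
  if (params$duration < 0.212 || params$duration > 0.860) {
    stop("spike-wave duration must lie in [0.212, 0.860] s")
  }
  n <- round(params$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  sw <- params$spike_width
  c1 <- sw * 0.45
  spike <- exp(-((t - c1) / (sw / 4))^2) -
    0.55 * exp(-((t - c1 - sw / 2.5) / (sw / 2))^2)
  wave <- numeric(n)
  in_wave <- t >= sw
  if (any(in_wave)) {
    u <- (t[in_wave] - sw) / (params$duration - sw)
    wave[in_wave] <- (params$wave_amplitude / params$spike_amplitude) *
      sin(pi * pmin(1, u)^params$asymmetry)
  }
  w <- spike + wave
  w <- w / max(abs(w)) * params$spike_amplitude * params$polarity
  w
}

#' Inject spike-wave events into a recording
#'
#' Adds events drawn from the given families at roughly `rate_per_min`
#' events per minute, with per-event multiplicative amplitude and duration
#' jitter. Events are placed on a jittered regular grid so that they never
#' overlap; the full realized parameters are returned as ground truth.
#'
#' @param rec A 100 Hz common-reference `eeg_recording`.
#' @param families List of [spike_wave_params()] objects.
#' @param rate_per_min Target event rate (events/minute).
#' @param jitter List with `amplitude` and `duration` fractional jitter.
#' @param seed Integer seed.
#' @param config Montage config (for neighbour spread).
#' @return List with `recording` (events added) and `truth`, a tibble with
#'   one row per injected event: `recording_id`, `onset_s`, `duration_s`,
#'   `family_id`, `amplitude`, `polarity`, `focus_channels` (list-column),
#'   `spread_channels` (list-column).
#' @export
inject_events <- function(rec, families, rate_per_min = 1,
                          jitter = list(amplitude = 0.25, duration = 0.08),
                          seed = 1, config = montage_config()) {
  stopifnot(inherits(rec, "eeg_recording"), rec$sample_rate == 100)
  fs <- rec$sample_rate
  dur_min <- rec_duration(rec) / 60
  n_events <- round(rate_per_min * dur_min)
  truth <- tibble::tibble(
    recording_id = character(), onset_s = numeric(), duration_s = numeric(),
    family_id = character(), amplitude = numeric(), polarity = numeric(),
    focus_channels = list(), spread_channels = list()
  )
  if (n_events == 0 || !length(families)) {
    return(list(recording = rec, truth = truth))
  }
  slot <- rec_duration(rec) / n_events
  sig <- rec$signal
  rows <- .with_seed(seed, {
    lapply(seq_len(n_events), function(k) {
      fam <- families[[sample.int(length(families), 1)]]
      amp_j <- stats::runif(1, 1 - jitter$amplitude, 1 + jitter$amplitude)
      dur_j <- stats::runif(1, 1 - jitter$duration, 1 + jitter$duration)
      # realized duration snapped to the 100 Hz sample grid so the ground
      # truth describes the injected waveform exactly
      dur <- min(0.860, max(0.212, fam$duration * dur_j))
      dur <- min(0.86, max(0.22, round(dur * fs) / fs))
      lo <- 0.1 * slot
      hi <- max(lo + 0.01, 0.9 * slot - dur)
      onset <- (k - 1) * slot + stats::runif(1, lo, hi)
      list(fam = fam, amp_j = amp_j, dur = dur,
           onset = round(onset * fs) / fs)
    })
  })
  lap <- config$laplacian
  out <- lapply(rows, function(r) {
    fam <- r$fam
    p <- fam
    p$duration <- r$dur
    p$spike_amplitude <- fam$spike_amplitude * r$amp_j
    p$wave_amplitude <- fam$wave_amplitude * r$amp_j
    w <- make_spike_wave(do.call(
      spike_wave_params,
      p[setdiff(names(p), character())]
    ), fs)
    i0 <- round(r$onset * fs) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    spread <- setdiff(
      intersect(unique(unlist(lap[fam$focus_channels])), rec$channel_labels),
      fam$focus_channels
    )
    for (ch in fam$focus_channels) sig[ch, idx] <<- sig[ch, idx] + w
    for (ch in spread) sig[ch, idx] <<- sig[ch, idx] + w * fam$spread_attenuation
    tibble::tibble(
      recording_id = rec$recording_id, onset_s = r$onset,
      duration_s = length(w) / fs, family_id = fam$family_id,
      amplitude = p$spike_amplitude, polarity = fam$polarity,
      focus_channels = list(fam$focus_channels),
      spread_channels = list(spread)
    )
  })
  truth <- dplyr::bind_rows(out)
  list(
    recording = eeg_recording(sig, rec$channel_labels, fs,
                              rec$montage, rec$recording_id),
    truth = truth
  )
}

#' Dataset specification for the synthetic generator
#'
#' Desk-scale defaults: 3 training and 3 evaluation recordings of 5 minutes
#' each at one injected event per minute, drawn from 4 spike-wave families.
#'
#' @param n_train,n_eval Numbers of recordings.
#' @param duration_s Recording length in seconds.
#' @param n_families Number of distinct spike-wave families.
#' @param rate_per_min Injected event rate.
#' @param native_rate Rate the recordings are generated/stored at (Hz).
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_train = 3, n_eval = 3, duration_s = 300,
                         n_families = 4, rate_per_min = 1,
                         native_rate = 100) {
  stopifnot(n_train >= 1, n_eval >= 1, duration_s > 0, n_families >= 1)
  structure(list(n_train = n_train, n_eval = n_eval, duration_s = duration_s,
                 n_families = n_families, rate_per_min = rate_per_min,
                 native_rate = native_rate),
            class = "dataset_spec")
}

# random spike-wave families: adjacent electrode pairs as foci,
# predominantly surface-negative spikes (clinical convention)
.draw_families <- function(n_families, config = montage_config()) {
  anterior <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T3", "C3", "Cz", "C4", "T4")
  lapply(seq_len(n_families), function(k) {
    e1 <- sample(anterior, 1)
    e2 <- sample(intersect(unlist(config$laplacian[[e1]]), anterior), 1)
    spike_wave_params(
      duration = stats::runif(1, 0.30, 0.70),
      spike_amplitude = stats::runif(1, 100, 160),
      wave_amplitude = stats::runif(1, 50, 80),
      polarity = sample(c(-1, 1), 1, prob = c(0.7, 0.3)),
      asymmetry = stats::runif(1, 0.8, 1.3),
      focus_channels = c(e1, e2),
      spread_attenuation = stats::runif(1, 0.3, 0.5),
      spike_width = stats::runif(1, 0.035, 0.06),
      family_id = paste0("family-", k)
    )
  })
}

#' Generate a complete synthetic training + evaluation dataset
#'
#' Training recordings come with channel-level annotations (events are
#' marked on their focus channels, where the discharge is clearest), as
#' channel-level marks are what template extraction needs. Evaluation
#' recordings come with onset/duration-only annotations (`channel = NA`),
#' mirroring how evaluation marks are typically made, plus the full ground
#' truth for the simulated reviewer. Jitter draws differ between training
#' and evaluation, so evaluation events are never byte-copies of templates.
#'
#' @param spec A [dataset_spec()].
#' @param seed Integer seed; everything is a pure function of (spec, seed).
#' @return List with elements `families`, `training` (recordings,
#'   annotations) and `evaluation` (recordings, annotations, truth).
#' @export
make_dataset <- function(spec = dataset_spec(), seed = 1) {
  stopifnot(inherits(spec, "dataset_spec"))
  seeds <- .with_seed(seed, {
    fams <- .draw_families(spec$n_families)
    list(fams = fams,
         sub = sample.int(.Machine$integer.max - 1L,
                          2L * (spec$n_train + spec$n_eval)))
  })
  fams <- seeds$fams
  sub <- seeds$sub
  gen_one <- function(id, bg_seed, ev_seed) {
    bg <- generate_background(spec$duration_s, bg_seed,
                              sample_rate = spec$native_rate,
                              recording_id = id)
    inject_events(bg, fams, rate_per_min = spec$rate_per_min, seed = ev_seed)
  }
  train <- lapply(seq_len(spec$n_train), function(i) {
    gen_one(sprintf("train-%02d", i), sub[2 * i - 1], sub[2 * i])
  })
  off <- 2L * spec$n_train
  eval_ <- lapply(seq_len(spec$n_eval), function(i) {
    gen_one(sprintf("eval-%02d", i), sub[off + 2 * i - 1], sub[off + 2 * i])
  })

  train_truth <- dplyr::bind_rows(lapply(train, `[[`, "truth"))
  # events are marked on every channel where they are visible: focus
  # channels plus the neighbours receiving the attenuated discharge
  train_ann <- tidyr::unnest(
    dplyr::transmute(train_truth,
      recording_id = .data$recording_id,
      channel = purrr::map2(.data$focus_channels, .data$spread_channels, c),
      onset_s = .data$onset_s, duration_s = .data$duration_s, label = "ied"
    ),
    "channel"
  )
  eval_truth <- dplyr::bind_rows(lapply(eval_, `[[`, "truth"))
  eval_ann <- dplyr::transmute(eval_truth,
    recording_id = .data$recording_id, channel = NA_character_,
    onset_s = .data$onset_s, duration_s = .data$duration_s, label = "ied"
  )
  list(
    families = fams,
    training = list(
      recordings = lapply(train, `[[`, "recording"),
      annotations = train_ann
    ),
    evaluation = list(
      recordings = lapply(eval_, `[[`, "recording"),
      annotations = eval_ann,
      truth = eval_truth
    )
  )
}
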