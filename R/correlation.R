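# Fourier-accelerated sliding Pearson correlation.
# The numerator is a circular cross-correlation computed by FFT; window
# means/variances come from running sums, so every position i carries the
# exact Pearson correlation between the template and signal[i, i+m).

#' Sliding Pearson correlation of a template against a signal
#'
#' Value at position `i` (1-based) is the Pearson correlation between
#' `waveform` and `signal[i:(i + m - 1)]`, for `i = 1 ..
#' length(signal) - m + 1`. Computed via FFT cross-correlation with
#' running-sum normalization; zero-variance windows (flat signal) yield 0.
#'
#' @param signal Numeric vector, length >= template length.
#' @param waveform Numeric template vector (length m >= 2).
#' @return Numeric vector of length `length(signal) - m + 1`, values in
#'   \[-1, 1\].
#' @export
sliding_correlation <- function(signal, waveform) {
  m <- length(waveform)
  n <- length(signal)
  stopifnot(m >= 2, n >= m)
  t0 <- waveform - mean(waveform)
  tn <- sqrt(sum(t0^2))
  n_out <- n - m + 1L
  if (tn == 0) return(numeric(n_out))
  N <- stats::nextn(n)
  X <- stats::fft(c(signal, numeric(N - n)))
  Tf <- stats::fft(c(t0, numeric(N - m)))
  cc <- Re(stats::fft(X * Conj(Tf), inverse = TRUE))[seq_len(n_out)] / N
  .normalize_cc(cc, signal, m, tn)
}

# turn raw cross-correlation numerators into Pearson correlations
.normalize_cc <- function(cc, signal, m, tn) {
  cs <- cumsum(signal)
  cs2 <- cumsum(signal^2)
  n_out <- length(cc)
  i <- seq_len(n_out)
  s1 <- cs[i + m - 1L] - c(0, cs)[i]
  s2 <- cs2[i + m - 1L] - c(0, cs2)[i]
  win_var <- s2 - s1^2 / m
  tol <- 1e-12 * m * max(s2[1], 1)
  degenerate <- win_var <= tol
  denom <- sqrt(pmax(win_var, tol)) * tn
  out <- cc / denom
  out[degenerate] <- 0
  pmin(1, pmax(-1, out))
}

# correlation traces for one template over all channels of a recording,
# reusing precomputed channel FFTs. ffts: list(N, n, X [N x C complex],
# cs, cs2 [n x C]).
.channel_ffts <- function(sig_matrix) {
  n <- ncol(sig_matrix)
  N <- stats::nextn(n)
  padded <- rbind(t(sig_matrix), matrix(0, N - n, nrow(sig_matrix)))
  list(
    N = N, n = n,
    X = stats::mvfft(padded),
    cs = apply(sig_matrix, 1L, cumsum),
    cs2 = apply(sig_matrix, 1L, function(x) cumsum(x^2))
  )
}

.trace_all_channels <- function(ffts, waveform) {
  m <- length(waveform)
  t0 <- waveform - mean(waveform)
  tn <- sqrt(sum(t0^2))
  n_out <- ffts$n - m + 1L
  C <- ncol(ffts$X)
  if (tn == 0 || n_out < 1L) return(matrix(0, max(n_out, 0L), C))
  Tf <- stats::fft(c(t0, numeric(ffts$N - m)))
  cc <- Re(stats::mvfft(ffts$X * Conj(Tf), inverse = TRUE))[seq_len(n_out), ,
                                                            drop = FALSE] / ffts$N
  out <- matrix(0, n_out, C)
  for (ch in seq_len(C)) {
    sig_cs <- ffts$cs[, ch]
    sig_cs2 <- ffts$cs2[, ch]
    i <- seq_len(n_out)
    s1 <- sig_cs[i + m - 1L] - c(0, sig_cs)[i]
    s2 <- sig_cs2[i + m - 1L] - c(0, sig_cs2)[i]
    win_var <- s2 - s1^2 / m
    tol <- 1e-12 * m * max(s2[1], 1)
    degenerate <- win_var <= tol
    denom <- sqrt(pmax(win_var, tol)) * tn
    v <- cc[, ch] / denom
    v[degenerate] <- 0
    out[, ch] <- pmin(1, pmax(-1, v))
  }
  out
}

# supra-threshold local maxima with non-maximum suppression over one
# template length: at most one candidate per underlying event per template
.find_candidates <- function(trace, m, threshold) {
  n <- length(trace)
  if (n == 0L) return(integer())
  above <- which(trace > threshold)
  if (!length(above)) return(integer())
  left <- c(-Inf, trace[-n])
  right <- c(trace[-1], -Inf)
  peaks <- above[trace[above] >= left[above] & trace[above] >= right[above]]
  if (!length(peaks)) return(integer())
  ord <- peaks[order(-trace[peaks], peaks)]
  kept <- integer()
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= m)) kept <- c(kept, p)
  }
  sort(kept)
}
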