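# Spectrogram front ends: short-time Fourier analysis at 8 ms hop, a
# 128-channel log-frequency (constant-Q-like) spectrogram, and bark-band
# energies for the loudness feature.

#' Short-time magnitude spectrogram
#'
#' Hann-windowed frames of 32 ms, hop of approximately 8 ms (the integer
#' sample count nearest to 8 ms), zero-padded FFT.
#'
#' @param x Mono waveform.
#' @param sample_rate Hz.
#' @param win_s Window length in seconds.
#' @param hop_s Hop in seconds.
#' @param nfft FFT size (default: next power of two above the window).
#' @return List with `mag` (frames x bins magnitude matrix), `freq` (Hz per
#'   bin), `t` (frame-center times, s), `hop` (samples).
#' @keywords internal
stft_mag <- function(x, sample_rate, win_s = 0.032, hop_s = 0.008, nfft = NULL) {
  win <- as.integer(round(win_s * sample_rate))
  hop <- as.integer(floor(hop_s * sample_rate))
  if (is.null(nfft)) nfft <- 2^ceiling(log2(win))
  n <- length(x)
  if (n < win) stop("input too short for one analysis window")
  starts <- seq(1L, n - win + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  idx <- outer(seq_len(win) - 1L, starts, "+")       # vectorised framing
  frames <- matrix(x[idx], nrow = win) * w
  frames <- rbind(frames, matrix(0, nfft - win, length(starts)))
  spec <- stats::mvfft(frames)
  keep <- seq_len(nfft %/% 2L + 1L)
  mag <- t(Mod(spec[keep, , drop = FALSE]))
  list(mag = mag, freq = (keep - 1L) * sample_rate / nfft,
       t = (starts - 1L + win / 2) / sample_rate, hop = hop)
}

# Triangular filterbank mapping linear-frequency bins onto `n_chan`
# log-spaced channels between f_lo and f_hi. Returns weights (bins x chan)
# and channel center frequencies.
logfreq_filterbank <- function(freq, n_chan = 128L, f_lo = 50,
                               f_hi = max(freq) * 0.97) {
  lc <- seq(log2(f_lo), log2(f_hi), length.out = n_chan + 2L)
  centers <- 2^lc
  lf <- ifelse(freq > 0, log2(freq), -Inf)
  W <- matrix(0, length(freq), n_chan)
  for (c in seq_len(n_chan)) {
    l0 <- lc[c]; l1 <- lc[c + 1L]; l2 <- lc[c + 2L]
    up <- (lf - l0) / (l1 - l0)
    dn <- (l2 - lf) / (l2 - l1)
    W[, c] <- pmax(0, pmin(up, dn))
  }
  W <- sweep(W, 2L, pmax(colSums(W), 1e-12), "/")
  list(weights = W, centers = centers[2L:(n_chan + 1L)],
       chan_per_oct = n_chan / (lc[n_chan + 1L] - lc[2L]))
}

#' Log-frequency spectrogram
#'
#' Magnitude STFT pooled onto 128 log-spaced frequency channels; the input
#' representation for the spectrotemporal modulation (rate-scale) analysis.
#'
#' @param x Mono waveform.
#' @param sample_rate Hz.
#' @param n_chan Number of channels.
#' @param f_lo Lowest channel center (Hz).
#' @return List with `spec` (frames x channels), `centers` (Hz),
#'   `chan_per_oct`, `t`, `frame_step` (s).
#' @export
logfreq_spectrogram <- function(x, sample_rate, n_chan = 128L, f_lo = 50) {
  s <- stft_mag(x, sample_rate)
  fb <- logfreq_filterbank(s$freq, n_chan = n_chan, f_lo = f_lo)
  list(spec = s$mag %*% fb$weights, centers = fb$centers,
       chan_per_oct = fb$chan_per_oct, t = s$t,
       frame_step = s$hop / sample_rate)
}

# Traunmueller/Zwicker critical-band rate.
hz_to_bark <- function(f) 13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2)

# Power pooled into 24 bark bands: frames x 24.
bark_band_energy <- function(mag, freq) {
  z <- pmin(floor(hz_to_bark(freq)) + 1L, 24L)
  pow <- mag^2
  out <- matrix(0, nrow(mag), 24L)
  for (b in seq_len(24L)) {
    sel <- z == b
    if (any(sel)) out[, b] <- rowSums(pow[, sel, drop = FALSE])
  }
  out
}
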