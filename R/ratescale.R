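# Spectrotemporal modulation (rate-scale) decomposition of a log-frequency
# spectrogram: a 2-D modulation filterbank with constant-Q Gaussian bands at
# signed temporal rates {+-2, 4, 8, 16, 32, 64} Hz and spectral scales
# {0.25, 0.5, 1, 2, 4, 8} cyc/oct. Filtering is done in the 2-D Fourier
# domain of the spectrogram; the complex band output's magnitude, averaged
# over frequency channels, gives the per-frame modulation energy envelope.

default_rates <- c(2, 4, 8, 16, 32, 64)
default_scales <- c(0.25, 0.5, 1, 2, 4, 8)

# Constant-Q log-domain Gaussian response centered at `c0` (> 0), evaluated
# on positive axis values `v`; sd of half an octave.
logq_response <- function(v, c0, sd_oct = 0.5) {
  out <- numeric(length(v))
  pos <- v > 0
  out[pos] <- exp(-0.5 * (log2(v[pos] / c0) / sd_oct)^2)
  out
}

#' Rate-scale decomposition of a log-frequency spectrogram
#'
#' @param spec Frames x channels log-frequency spectrogram (magnitudes).
#' @param frame_step Frame step in seconds.
#' @param chan_per_oct Channels per octave of the spectrogram.
#' @param rates Positive rate centers in Hz (signed bands are formed as
#'   +-rate).
#' @param scales Scale centers in cyc/oct.
#' @return List with `energy` — an array `T x (2*length(rates)) x
#'   length(scales)` of modulation energy envelopes — plus `rates` (signed,
#'   negative first) and `scales`.
#' @export
rate_scale_energy <- function(spec, frame_step, chan_per_oct,
                              rates = default_rates, scales = default_scales) {
  spec <- as.matrix(spec)
  Tn <- nrow(spec); Fn <- ncol(spec)
  # remove the per-channel mean so rate-0 (DC) leakage does not dominate
  spec0 <- sweep(spec, 2L, colMeans(spec), "-")
  # zero-pad the time axis to a 2-3-5-smooth length: R's mixed-radix FFT
  # needs smooth lengths to stay O(n log n)
  T2 <- stats::nextn(Tn, c(2L, 3L, 5L))
  if (T2 > Tn) spec0 <- rbind(spec0, matrix(0, T2 - Tn, Fn))
  Y <- stats::fft(spec0)                      # 2-D FFT (T2 x F)
  # signed frequency axes with wraparound
  wt <- (seq_len(T2) - 1L) / (T2 * frame_step)
  wt <- ifelse(wt > 1 / (2 * frame_step), wt - 1 / frame_step, wt)   # Hz
  wf <- (seq_len(Fn) - 1L) * chan_per_oct / Fn
  wf <- ifelse(wf > chan_per_oct / 2, wf - chan_per_oct, wf)         # cyc/oct
  signed_rates <- c(-rev(rates), rates)
  energy <- array(0, dim = c(Tn, length(signed_rates), length(scales)))
  gss <- lapply(scales, function(s) logq_response(wf, s))
  # the time-axis inverse transform commutes with scaling the spectral-
  # modulation columns, so it is done once per rate; the short frequency-
  # axis transform is then applied per scale
  for (ri in seq_along(signed_rates)) {
    r <- signed_rates[ri]
    gr <- logq_response(sign(r) * wt, abs(r))
    Ar <- stats::mvfft(Y * gr, inverse = TRUE) / T2      # T2 x Fn
    for (si in seq_along(scales)) {
      zt <- stats::mvfft(t(Ar) * gss[[si]], inverse = TRUE) / Fn  # Fn x T2
      energy[, ri, si] <- colMeans(Mod(zt[, seq_len(Tn), drop = FALSE]))
    }
  }
  list(energy = energy, rates = signed_rates, scales = scales)
}
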