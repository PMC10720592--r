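# The sixteen low-level acoustic features: energy (LD, SE, RSE), spectral
# shape (BR, BW, FL, IR), pitch and harmonicity (P, H), and spectrotemporal
# modulation statistics (MS, CS, MR, HR, LR, CR, CAR). Features are
# computed on 8 ms frames, mean-pooled onto the exact 64 ms analysis grid,
# and z-scored per scene.

FEATURE_NAMES <- c("LD", "SE", "RSE", "BR", "BW", "FL", "IR", "P", "H",
                   "MS", "CS", "MR", "HR", "LR", "CR", "CAR")

# Harmonic-sieve pitch estimate: candidates 50-800 Hz in 1/24-octave steps,
# harmonics 1..10 weighted 1/h, nearest-bin sampling of the magnitude
# spectrum. Returns per-frame pitch (Hz) and a normalised match score.
harmonic_sieve <- function(mag, freq, f0_lo = 50, f0_hi = 800) {
  cands <- 2^seq(log2(f0_lo), log2(f0_hi), by = 1 / 24)
  df <- freq[2L] - freq[1L]
  nb <- length(freq)
  hw <- 1 / seq_len(10L)
  scores <- matrix(0, nrow(mag), length(cands))
  for (ci in seq_along(cands)) {
    bins <- round(cands[ci] * seq_len(10L) / df) + 1L
    ok <- bins >= 1L & bins <= nb
    if (!any(ok)) next
    scores[, ci] <- mag[, bins[ok], drop = FALSE] %*% hw[ok]
  }
  tot <- rowSums(mag) + 1e-12
  best <- max.col(scores, ties.method = "first")
  list(pitch = cands[best],
       harmonicity = scores[cbind(seq_len(nrow(mag)), best)] / tot)
}

frame_features_8ms <- function(x, sample_rate, n_chan = 128L) {
  s <- stft_mag(x, sample_rate)
  mag <- s$mag
  pow <- mag^2
  eps <- 1e-12
  tot_mag <- rowSums(mag) + eps
  # spectral shape on the linear-frequency magnitude spectrum
  BR <- as.numeric(mag %*% s$freq) / tot_mag
  BW <- sqrt(rowSums(mag * sweep(outer(rep(1, nrow(mag)), s$freq), 1L, BR, "-")^2) / tot_mag)
  lm <- log(mag + eps)
  FL <- exp(rowMeans(lm)) / (rowMeans(mag) + eps)
  IR <- rowSums(t(diff(t(lm)))^2) / (rowSums(lm^2) + eps)
  SE <- rowMeans(pow)
  LD <- rowMeans(bark_band_energy(mag, s$freq))
  hs <- harmonic_sieve(mag, s$freq)
  # rate-scale statistics on the log-frequency spectrogram
  fb <- logfreq_filterbank(s$freq, n_chan = n_chan)
  lspec <- mag %*% fb$weights
  rs <- rate_scale_energy(lspec, frame_step = s$hop / sample_rate,
                          chan_per_oct = fb$chan_per_oct)
  E <- rs$energy
  rate_marg <- apply(E, c(1L, 2L), mean)             # T x signed rates
  scale_marg <- apply(E, c(1L, 3L), mean)            # T x scales
  abs_rates <- abs(rs$rates)
  uniq_ar <- sort(unique(abs_rates))
  rate_abs <- sapply(uniq_ar, function(a) rowSums(rate_marg[, abs_rates == a, drop = FALSE]))
  RSE <- rowMeans(rate_marg)
  MS <- apply(scale_marg, 1L, max)
  CS <- as.numeric(scale_marg %*% rs$scales) / (rowSums(scale_marg) + eps)
  MR <- apply(rate_abs, 1L, max)
  HR <- rowMeans(rate_abs[, uniq_ar > 20, drop = FALSE])
  LR <- rowMeans(rate_abs[, uniq_ar <= 20, drop = FALSE])
  CR <- as.numeric(rate_marg %*% rs$rates) / (rowSums(rate_marg) + eps)
  CAR <- as.numeric(rate_marg %*% abs_rates) / (rowSums(rate_marg) + eps)
  silent <- tot_mag <= 1e-9
  out <- cbind(LD = LD, SE = SE, RSE = RSE, BR = BR, BW = BW, FL = FL,
               IR = IR, P = hs$pitch, H = hs$harmonicity, MS = MS, CS = CS,
               MR = MR, HR = HR, LR = LR, CR = CR, CAR = CAR)
  out[silent, c("P", "H", "BR", "BW", "FL", "IR", "CS", "CR", "CAR")] <- 0
  list(values = out, t = s$t)
}

#' Compute the 16-feature acoustic representation of a scene
#'
#' Features are computed on 8 ms frames, mean-pooled onto the exact 64 ms
#' grid (frames assigned to 64 ms bins by their center time), and z-scored
#' per scene. Constant feature columns z-score to zeros with a warning.
#'
#' @param waveform Mono numeric waveform. Stereo input (a matrix with more
#'   than one column) is rejected: mix or split first.
#' @param sample_rate Hz.
#' @param scene_id Identifier stored in the result.
#' @param zscore Z-score per scene (default `TRUE`). The pooled pre-z-score
#'   values are always kept in the `raw` field.
#' @param n_chan Log-frequency channels for the modulation analysis.
#' @return A `feature_matrix`: list with `scene_id`, `frame_step` (0.064),
#'   `names`, `values` (T x 16, z-scored when requested), `raw` (T x 16
#'   pooled pre-z-score values), `zscored`.
#' @export
featurize <- function(waveform, sample_rate, scene_id = "scene",
                      zscore = TRUE, n_chan = 128L) {
  if (is.matrix(waveform) && ncol(waveform) > 1L) {
    stop("stereo input: mix to mono or featurize channels separately")
  }
  waveform <- as.numeric(waveform)
  if (length(waveform) < sample_rate) stop("input must be at least 1 s long")
  ff <- frame_features_8ms(waveform, sample_rate, n_chan = n_chan)
  # pool 8 ms frames onto the exact 64 ms grid by bin membership
  bin <- floor(ff$t / 0.064) + 1L
  nb <- max(bin)
  pooled <- apply(ff$values, 2L, function(col) {
    as.numeric(tapply(col, bin, mean))
  })
  # drop a trailing bin holding fewer than half the usual frame count
  full <- tabulate(bin)
  if (full[nb] < max(full) / 2 && nb > 1L) pooled <- pooled[-nb, , drop = FALSE]
  vals <- if (zscore) zscore_cols(pooled) else pooled
  structure(list(scene_id = scene_id, frame_step = 0.064,
                 names = FEATURE_NAMES, values = vals, raw = pooled,
                 zscored = zscore),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> scene %s: %d frames x %d features @ 64 ms%s\n",
              x$scene_id, nrow(x$values), ncol(x$values),
              if (x$zscored) ", z-scored" else ""))
  invisible(x)
}

#' Construct a feature matrix from precomputed values
#'
#' Wraps an arbitrary numeric matrix on the 64 ms grid in the container used
#' by the regression stages; the route for synthetic feature streams.
#'
#' @param values Numeric T x F matrix.
#' @param scene_id Identifier.
#' @param frame_step Seconds per frame.
#' @param names Column names (defaults to the matrix column names or F1..).
#' @param zscore Z-score the columns.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, scene_id = "scene", frame_step = 0.064,
                           names = NULL, zscore = FALSE) {
  values <- as.matrix(values)
  if (is.null(names)) {
    names <- colnames(values) %||% paste0("F", seq_len(ncol(values)))
  }
  colnames(values) <- names
  vals <- if (zscore) zscore_cols(values) else values
  structure(list(scene_id = scene_id, frame_step = frame_step, names = names,
                 values = vals, raw = values, zscored = zscore),
            class = "feature_matrix")
}

#' Write a feature matrix as CSV
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path) {
  df <- data.frame(t = (seq_len(nrow(fm$values)) - 1L) * fm$frame_step,
                   fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
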