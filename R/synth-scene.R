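# Synthetic audio scenes with planted acoustic events.
#
# The generator emulates the study stimuli: 2-minute natural scenes with
# discrete acoustically conspicuous events, resampled to 22.05 kHz and
# normalised to the RMS energy of the loudest 1% of the scene.

#' Specify a synthetic audio scene
#'
#' A scene is a stationary noise background (with an optional spectral tilt)
#' plus a list of planted events, each stepping the local level by
#' `level_step` dB above the background. Event kinds:
#' \describe{
#'   \item{tone}{pure tone at `carrier` Hz}
#'   \item{am_tone}{tone at `carrier` Hz, sinusoidally amplitude-modulated at
#'     `mod_rate` Hz (modulation depth 1)}
#'   \item{noise_burst}{white noise burst}
#'   \item{ripple}{spectrotemporal ripple: a bank of log-spaced tones with a
#'     drifting sinusoidal spectral envelope (`mod_rate` Hz drift)}
#' }
#'
#' @param scene_id Scene identifier string.
#' @param duration Scene duration in seconds (> 10).
#' @param sample_rate Sampling rate in Hz (default 22050).
#' @param noise_level_db Background level in dB relative to full scale;
#'   `-Inf` means a silent background.
#' @param spectral_tilt Background spectral tilt in dB/octave (0 = white).
#' @param events A data.frame with columns `onset`, `duration`, `kind`,
#'   `level_step`, and optionally `carrier`, `mod_rate`; or `NULL`.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(scene_id, duration, sample_rate = 22050L,
                       noise_level_db = -30, spectral_tilt = 0,
                       events = NULL) {
  assert_scalar_num(duration, "duration")
  if (duration <= 10) stop("`duration` must exceed 10 s")
  if (is.null(events)) {
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         kind = character(0), level_step = numeric(0),
                         carrier = numeric(0), mod_rate = numeric(0))
  }
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("onset", "duration", "kind", "level_step") %in% names(events))) {
      stop("`events` needs columns onset, duration, kind, level_step")
    }
    if (is.null(events$carrier)) events$carrier <- 1000
    if (is.null(events$mod_rate)) events$mod_rate <- 8
    if (is.unsorted(events$onset, strictly = TRUE)) {
      stop("planted event onsets must be strictly increasing")
    }
    if (any(events$onset < 0) || any(events$onset + events$duration > duration)) {
      stop("all planted events must lie inside [0, duration]")
    }
    bad <- !events$kind %in% c("tone", "am_tone", "noise_burst", "ripple")
    if (any(bad)) stop("unknown event kind: ", paste(events$kind[bad], collapse = ", "))
    # overlapping events of the same kind are ambiguous in the ground truth
    for (k in unique(events$kind)) {
      e <- events[events$kind == k, , drop = FALSE]
      if (nrow(e) > 1L) {
        off <- e$onset + e$duration
        if (any(e$onset[-1L] < off[-nrow(e)])) {
          stop("overlapping planted events of kind '", k,
               "' are not allowed; stagger their onsets or change the kind")
        }
      }
    }
  }
  structure(list(scene_id = as.character(scene_id), duration = duration,
                 sample_rate = as.integer(sample_rate),
                 noise_level_db = noise_level_db,
                 spectral_tilt = spectral_tilt, events = events),
            class = "scene_spec")
}

# Tilted (1/f^alpha-style) Gaussian noise via spectral shaping.
tilted_noise <- function(n, tilt_db_per_oct) {
  x <- stats::rnorm(n)
  if (tilt_db_per_oct == 0) return(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1L))              # avoid log(0) at DC
  f <- pmin(f, n - f + 1)                 # mirrored frequency index
  gain <- 10^((tilt_db_per_oct * log2(f)) / 20)
  gain <- gain / sqrt(mean(gain^2))
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

event_samples <- function(kind, n, fs, carrier, mod_rate) {
  t <- (seq_len(n) - 1L) / fs
  switch(kind,
    tone = sin(2 * pi * carrier * t),
    am_tone = sin(2 * pi * carrier * t) * (1 + sin(2 * pi * mod_rate * t)) / 2,
    noise_burst = stats::rnorm(n) / 3,
    ripple = ripple_samples(n, fs, carrier, mod_rate),
    stop("unknown kind"))
}

# Proper ripple synthesis (kept separate for clarity).
ripple_samples <- function(n, fs, carrier, mod_rate, scale_cyc_oct = 1) {
  t <- (seq_len(n) - 1L) / fs
  fk <- carrier * 2^seq(0, 2, length.out = 40L)
  x_oct <- log2(fk / carrier)
  ph <- stats::runif(40L, 0, 2 * pi)
  s <- numeric(n)
  for (k in seq_along(fk)) {
    env <- 1 + sin(2 * pi * (mod_rate * t - scale_cyc_oct * x_oct[k]))
    s <- s + env * sin(2 * pi * fk[k] * t + ph[k])
  }
  s / length(fk) * 2
}

#' Generate a synthetic scene waveform with planted events
#'
#' Background noise and planted events are synthesised at the requested
#' level steps, 10 ms raised-cosine ramps are applied at event edges, and the
#' final waveform is normalised so that the RMS of the loudest 1% of 50 ms
#' frames equals `ref_rms` (see [normalize_loudest()]).
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed; fully determines the waveform.
#' @param ref_rms Reference RMS for the loudest 1% of frames.
#' @return List with `waveform` (numeric vector in \[-1, 1\]),
#'   `sample_rate`, and `truth` — a ground-truth record carrying
#'   `planted_onsets`, `planted_offsets`, `kinds`, and the normalisation gain.
#' @export
make_scene <- function(spec, seed = 1L, ref_rms = 0.1) {
  stopifnot(inherits(spec, "scene_spec"))
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration * fs))
  with_seed(seed, {
    if (is.finite(spec$noise_level_db)) {
      bg <- tilted_noise(n, spec$spectral_tilt) *
        10^(spec$noise_level_db / 20) / 3   # /3 keeps Gaussian peaks in range
    } else {
      bg <- numeric(n)
    }
    x <- bg
    ev <- spec$events
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        i0 <- as.integer(round(ev$onset[i] * fs)) + 1L
        len <- as.integer(round(ev$duration[i] * fs))
        i1 <- min(i0 + len - 1L, n)
        len <- i1 - i0 + 1L
        # event RMS sits exactly level_step dB above the background RMS
        # (a -40 dBFS floor stands in for a silent background)
        bg_rms <- if (is.finite(spec$noise_level_db)) {
          10^(spec$noise_level_db / 20) / 3
        } else 10^(-40 / 20)
        amp <- bg_rms * 10^(ev$level_step[i] / 20)
        s <- if (ev$kind[i] == "ripple") {
          ripple_samples(len, fs, ev$carrier[i], ev$mod_rate[i])
        } else {
          event_samples(ev$kind[i], len, fs, ev$carrier[i], ev$mod_rate[i])
        }
        s_rms <- sqrt(mean(s^2))
        if (s_rms > 0) s <- s / s_rms
        nr <- min(as.integer(0.01 * fs), len %/% 2L)
        if (nr > 0L) {
          ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
          s[seq_len(nr)] <- s[seq_len(nr)] * ramp
          s[(len - nr + 1L):len] <- s[(len - nr + 1L):len] * rev(ramp)
        }
        x[i0:i1] <- x[i0:i1] + amp * s
      }
    }
    norm <- normalize_loudest(x, fs, ref_rms = ref_rms)
    truth <- list(
      scene_id = spec$scene_id,
      planted_onsets = ev$onset,
      planted_offsets = ev$onset + ev$duration,
      kinds = ev$kind,
      level_steps = ev$level_step,
      gain = norm$gain,
      duration = spec$duration,
      sample_rate = fs
    )
    list(waveform = norm$x, sample_rate = fs, truth = truth)
  })
}

#' Normalise a waveform by the RMS of its loudest 1% of frames
#'
#' The waveform is cut into non-overlapping 50 ms frames; the frames whose
#' RMS falls in the top 1% define the scene's loud reference, and the whole
#' signal is scaled so that their pooled RMS equals `ref_rms`. The operation
#' is idempotent up to floating-point rounding.
#'
#' @param x Numeric waveform.
#' @param sample_rate Hz.
#' @param ref_rms Target RMS of the loudest 1% of frames.
#' @param frame_s Frame length in seconds (default 0.05).
#' @return List with the scaled waveform `x` and the applied `gain`.
#' @export
normalize_loudest <- function(x, sample_rate, ref_rms = 0.1, frame_s = 0.05) {
  flen <- max(1L, as.integer(round(frame_s * sample_rate)))
  nf <- length(x) %/% flen
  if (nf < 1L) stop("waveform shorter than one frame")
  m <- matrix(x[seq_len(nf * flen)], nrow = flen)
  rms <- sqrt(colMeans(m^2))
  k <- max(1L, ceiling(0.01 * nf))
  top <- sort(rms, decreasing = TRUE)[seq_len(k)]
  loud <- sqrt(mean(top^2))
  if (loud == 0) return(list(x = x, gain = 1))
  gain <- ref_rms / loud
  list(x = x * gain, gain = gain)
}

#' Write scene ground truth as a JSON sidecar
#'
#' @param truth Ground-truth record from [make_scene()] (or any list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path File path.
#' @return The ground-truth list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
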