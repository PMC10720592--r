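---
title: "Methods: behavioral auditory salience, from attention traces to predictive models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral auditory salience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audsal)
```

# The measurement model

Dichotic listening presents a different natural scene to each ear while the
listener continuously reports the attended side. Coding each trial as a
binary *attention-toward* trace for a given scene, the across-participant
mean of those traces is a time-resolved, population-level measure of how
strongly each moment of the scene captures attention. `audsal` implements
this analysis chain together with acoustic and semantic predictors of the
resulting salience map, a context-windowed ridge model that links them, and
an event-onset detection framework.

Playing the same scene time-reversed is the experimental control at the
heart of the design: reversal preserves short-term acoustics but scrambles
longer-term context and semantic identity. Events whose forward and
(re-reversed) backward responses coincide are attributable to low-level
acoustics; events where they diverge implicate context and meaning.

# Behavioral stage

**Quality control.** The per-trial switching rate (0/1 transitions per
second) is pooled over all trials; trials strictly outside the open
(10th, 90th) percentile interval are abnormal, and a participant is removed
when *more than five* trials are abnormal. Percentiles use the standard
linear-interpolation definition, so a degenerate cohort in which every
trial has the same rate excludes nobody — thresholds are open bounds.

**Average behavioral salience.** Each surviving trace is shifted 1 s
earlier (the average reaction-time delay), resampled to the 64 ms analysis
grid by zero-order hold, averaged across participants, and smoothed by
three passes of a centered 1.5 s moving average. Edge samples are
replicated for both the shift and the smoothing; the window length is
rounded to an odd number of frames (23) so the filter is symmetric. Three
box passes equal one convolution with a piecewise-quadratic kernel of
4.5 s support — the test-suite checks the impulse response against that
composed kernel analytically.

**Salient events.** The map derivative is the first-order difference per
frame. Onsets are strict local maxima of the derivative, offsets the next
local minimum; a plateau counts once, at its first sample, with plateaus
defined up to a 1e-9 numerical tolerance so that exactly-linear stretches
do not shed spurious extrema. Events whose offset never arrives are closed
at the scene end and flagged. Slope is the derivative at the onset in
salience units per 64 ms frame: on this scale a corpus of moderately
salient events has slopes of a few 1e-4 to a few 1e-2, and strength =
slope + consensus × P75(corpus slopes) has the same order, which is the
internally consistent reading of the strength definition (the alternative,
(slope + consensus) × P75, is orders of magnitude off and is rejected).

**Minimum-slope floor.** Onset candidacy requires the derivative to exceed
`min_slope` (default 1e-3 per frame). This default is deliberately far
above pure floating-point ripple: with realistic cohorts (lapse switches
at ~0.005/s, n ≈ 100–200), lapse shot noise leaves derivative wiggles of
order 1e-4 after smoothing, while a true event at consensus ≥ 0.05 exceeds
1.5e-3. A purely numerical floor (say 1e-6) would pass every lapse wiggle
and destroy the false-discovery behavior of the extractor; the default
therefore sits in the wide gap between noise and signal rather than at
machine precision.

**Reaction times.** Timelines are ambiguous once the map has been shifted;
the package adopts the convention that individual reaction times are
measured on the *shifted* traces relative to event onsets, searching
±1 s around the onset (the window's backward reach mirrors the shift).
Under this convention a simulator cohort with reaction-time median 0.9 s,
measured against its planted onsets, reports −0.1 s = 0.9 − 1.0; adding
back the 1 s adjustment recovers the natural scale, which is what the
acceptance script reports.

**Matching.** Backward events are reflected onto the forward axis
(onset′ = duration − offset, an involution), and each reference event takes
the maximum interval intersection with the other direction's events,
normalised by its own duration. Matching requires the score to *strictly*
exceed 0.5 — exactly half overlap is a mismatch. The threshold is a
parameter because nearby choices behave similarly.

# Acoustic features

Sixteen descriptors are computed on 8 ms frames and mean-pooled to the
64 ms grid. The short-time front end uses 32 ms Hann windows with a
176-sample hop (the integer closest to 8 ms at 22 050 Hz); pooling assigns
frames to exact 64 ms bins by their center time, so the feature grid never
drifts against the behavioral grid even though 8 ms is not an integer
sample count. The spectral shape group (brightness = centroid, bandwidth =
spread, flatness = geometric/arithmetic mean ratio, irregularity =
normalised squared difference of adjacent log magnitudes) is computed on
the linear-frequency magnitude spectrum; loudness is the mean energy of 24
bark bands; pitch and harmonicity come from a harmonic sieve over
fundamentals 50–800 Hz (1/24-octave steps, ten 1/h-weighted harmonics,
nearest-bin sampling — pitch resolution is therefore one FFT bin,
≈21.5 Hz).

The modulation group passes a 128-channel log-frequency spectrogram
(triangular pooling, 50 Hz upward) through a 2-D modulation filterbank:
constant-Q log-domain Gaussian bands (σ = 0.5 octave) at signed rates
±{2, 4, 8, 16, 32, 64} Hz and scales {0.25, 0.5, 1, 2, 4, 8} cyc/oct —
standard cortical-model defaults. Filtering happens in the 2-D Fourier
domain of the spectrogram; per (rate, scale) band the magnitude of the
complex band output, averaged over channels, is the energy envelope. High-
versus low-rate energy splits at 20 Hz; the rate centroid uses signed
rates (direction-sensitive) while its absolute-rate variant ignores
direction. Two numerical details matter: the per-channel mean is removed
before the 2-D transform so DC leakage cannot dominate the lowest bands,
and the time axis is zero-padded to a 2-3-5-smooth length because R's
mixed-radix FFT degrades to quadratic cost on lengths with large prime
factors (a 2-minute scene yields 15 029 frames, which is such a length).

z-scoring is per scene, after pooling; constant columns (e.g. silence)
z-score to zeros with a warning rather than dividing by zero.

**Feature changes** around an onset are mean(post) − mean(pre) over the
windows [+0.5, +1.0] s and [−1.0, −0.5] s. Window means integrate the
piecewise-linear interpolant of the frame samples exactly, so a ramp of
slope *m* through the onset yields precisely 1.5·m (the window centers are
1.5 s apart) — a discrete frame-selection mean would be biased by up to 2%
depending on how the window edges fall on the grid. Group statistics use
one-sample t-tests, a three-factor ANOVA (presentation × event type ×
feature, two-way interactions), and per-feature Tukey-HSD pairwise
contrasts, all via base R (`t.test`, `aov`, `TukeyHSD`).

# Semantic features

Any provider that returns per-layer embedding streams (`T × K_l` matrices
on a common grid) plugs into the pipeline; the package ships a synthetic
provider that plants mean shifts of known Euclidean norm at chosen change
points. Layer-wise surprisal is the distance between the current frame and
the mean of the strictly-past 4 s window (`t−W … t−1`; including the
current frame would deflate every value by a factor (W−1)/W). Warm-up
frames use the partial history and are flagged rather than dropped — losing
4 s of every scene would bias segment evaluation near scene starts.

Dominant-class labeling averages leaf posteriors over a segment, keeps the
top 10 leaves (ties broken by lexicographic id for determinism), sums
candidate posteriors into their root classes (Human, Things, Music,
Animals, Background), and returns the argmax root; an all-zero segment is
a flagged deterministic tie. The leaf-to-root table is user-supplied (the
synthetic taxonomy maps ids by prefix); ambiguous and channel/environment
sounds belong in Background.

# The salience regression model

The model predicts the salience map from temporally windowed features,

$$\hat r_t = W_a^\top a_t + W_s^\top s_t + b,$$

where $a_t$ and $s_t$ stack per-block smoothed features over past and
future context lags on the 64 ms grid. The fit minimises squared error
with separate L2 penalties $\lambda_a\|W_a\|^2 + \lambda_s\|W_s\|^2$; the
bias is unpenalised. The solution is closed-form with a diagonal penalty
matrix; an unpenalised singular system falls back to the Moore–Penrose
pseudoinverse with a warning. The test-suite pins this solver to an
independent gradient-descent oracle at 1e-6 and to exact recovery of
noise-free linear ground truth.

Defaults when no tuning corpus is given: 0.5 s acoustic and 1 s semantic
smoothing, 4 s past and 1 s future context, λ grids logarithmic over
1e-4…1e4 — repository defaults, selectable by scene-fold cross-validation
(`cross_validate()` splits by scene, never by frame, so temporal leakage
across folds is impossible).

Model variants fix the feature blocks and context caps: A-only (acoustic,
≤0.5 s), A-C (acoustic, ≤4 s), A-S (acoustic + surprisal context), S
(surprisal only — implemented as a single-block ridge on the surprisal
stream). Evaluation is the Pearson correlation within 8 s segments hopped
by 4 s, skipping 1 s at each scene edge; segments take the event category
(match/mismatch/no-event) with the larger total overlap, no-event segments
are reported but excluded from match/mismatch tests, and zero-variance
segments are excluded and counted. Layer ablations add surprisal layers
cumulatively and compare against baselines whose added layers are white
noise (averaged over ≥10 seeds); temporal-response-function analysis
reshapes $W_a$ to lag × feature and sets it against the features'
normalised autocorrelations.

# Onset detection

The detector answers a different question — *when* do events start — with
a deliberately small model: features are first-differenced, each 1 s
segment (16 frames; half-open intervals decide boundary onsets) is scored
by `sigmoid(vᵀ X u + b)` with one temporal weight vector shared across all
features and per-feature combination weights. The A-S variant prepends 3 s
of past context and stacks the surprisals under the acoustic features;
first-differenced channels are standardised per scene so SGD sees
comparable scales. Training is plain minibatch SGD (batch 200, learning
rate 0.01, 100 epochs) on cross-entropy, keeping the epoch snapshot with
the lowest full-training loss; because the bilinear loss is non-convex the
fit runs three seeded random restarts and keeps the best. ROC curves sweep
all unique scores; the trapezoidal AUROC equals the Mann–Whitney
normalisation, which the tests verify to 1e-10 (and cross-check against
pROC where available). Signal baselines (tagging-posterior change,
interobserver counts) are max-pooled per segment — onset signals are
pulses, so the maximum, not the mean, carries them.

Chance-level checks train on permuted labels and score *held-out*
segments: an expressive model scored on its own shuffled training labels
sits above 0.5 by construction, so the held-out protocol is the honest
null.

# The synthetic study

The generator's defaults emulate the study conditions end to end: 2-minute
scenes, ~100 participants per direction, consensus ≈ 0.45 per event,
reaction times with 0.9 s median and 0.14 s spread (a shifted log-normal —
only the median and spread are constrained, and the log-normal supplies
the realistic right skew), spurious lapse switches at 0.005/s (brief
excursions of 0.1–1 s), and traces sampled at a cursor-like 20 Hz before
zero-order-hold resampling. Participants attend for a `hold` duration
after responding (default 2.5 s, matching the observed mean event
duration); `hold = Inf` reproduces the degenerate keep-attending-forever
cohort used in some closed-form tests. Audio scenes are tilted-noise
backgrounds with planted tones, AM tones, noise bursts and moving ripples
whose RMS sits exactly `level_step` dB above the background, normalised so
the loudest 1% of 50 ms frames has a fixed reference RMS (the paper-style
loudness normalisation; the operation is idempotent to rounding).

What the generator does *not* emulate: cursor kinematics and the center
zone of the response interface (traces arrive pre-binarised), attentional
inertia or cross-scene competition (each trace depends only on its own
scene's events), and any acoustic realism beyond what the feature bank
measures. Passing tests therefore validate the analysis pipeline and its
statistical behavior on known ground truth — they do not certify
psychoacoustic claims about real listeners.

Linear ground-truth maps are affinely rescaled into [0, 1] rather than
clipped, so the generating filter stays exactly recoverable; the
filter-recovery experiment (20 scenes × 120 s at SNR 10) demands cosine
similarity ≥ 0.9 between generating and recovered filters.

# Problem sizes and determinism

The shipped test-suite and acceptance script run everything at sizes a
laptop handles in minutes: the recovery experiment uses 20 × 1875 frames,
the context-benefit experiments 20 seeds of 6 scenes × 60 s, the full
synthetic study 8 scenes × 120 s of audio. All randomness flows through
per-stage child seeds derived from one master seed; the whole pipeline run
twice with the same configuration produces byte-identical artifacts, which
is itself one of the tested guarantees.

# Known limitations

* Pitch resolution is one FFT bin (≈21.5 Hz) — adequate for feature-change
  statistics, not for music-grade pitch tracking.
* The modulation filterbank is a self-contained cortical-style
  implementation with pinned defaults; absolute energies will differ from
  other cortical-model implementations, though band orderings and
  centroids behave identically on test stimuli.
* The S-model reuses the acoustic design machinery with surprisals in the
  single block; its penalty is therefore labelled λₐ internally.
* Offset quality is not modelled: behavioral offsets are imprecise, and
  the detector predicts onsets only (the label schema leaves room for a
  3-way onset/offset/during extension).
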