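# audsal — behavioral auditory salience analysis

`audsal` is an R package for analysing **continuous behavioral measures of
auditory salience** collected with dichotic listening experiments. In this
paradigm a listener hears a different natural scene in each ear and
continuously reports which side holds their attention; the binary
attention-toward traces of many listeners, pooled per scene, form a
time-resolved behavioral map of what stands out in a soundscape. Presenting
each scene both forward and time-reversed separates events whose salience is
carried by instantaneous acoustics (similar responses in both directions)
from events driven by longer-term context and semantics (responses that
diverge).

The package implements the full analysis chain:

1. **Behavioral maps** — quality control by switching-rate percentiles,
   reaction-time adjustment (1 s), across-participant averaging, and three
   1.5 s moving-average passes produce the *average behavioral salience*
   `r_t ∈ [0, 1]` on a 64 ms grid.
2. **Salient events** — onsets are local maxima of the map derivative,
   offsets the following derivative minima; each event carries a slope,
   an absolute consensus (peak salience), a duration, and a strength
   `slope + consensus · P75(all onset slopes)`. Forward and time-reversed
   events are matched by >50% normalised interval overlap.
3. **Acoustic features** — a bank of 16 descriptors on 8 ms frames pooled
   to 64 ms: bark-band loudness, spectral energy, brightness, bandwidth,
   flatness, irregularity, pitch and harmonicity by harmonic-template
   matching, and spectrotemporal modulation statistics (rate/scale energies
   and centroids) from a 128-channel log-frequency spectrogram passed
   through a 2-D modulation filterbank (rates ±2…64 Hz, scales
   0.25…8 cyc/oct).
4. **Semantic surprisal** — for any deep audio-embedding stream (an
   adapter contract; a synthetic provider ships with the package), the
   per-layer surprisal `s_{l,t} = ‖y_{l,t} − mean(y_{l,t−W…t−1})‖₂` over a
   4 s past window, plus AudioSet-style dominant-class labeling by belief
   propagation of leaf posteriors to five root classes.
5. **Salience regression** — the core model:

   `r̂_t = Wₐᵀ a_t + Wₛᵀ s_t + b`

   a block-ridge regression on temporally windowed (past/future context)
   acoustic and semantic features, with separate penalties `λₐ, λₛ`, fitted
   in closed form by `fit_salience()` (an S3 model with `print`, `summary`,
   `coef`, `predict`, `residuals`, `plot` methods). Model variants A-only
   (0.5 s context), A-C (4 s context), A-S (acoustic + semantic), and S
   (surprisal only) are evaluated by Pearson correlation on 8 s segments
   (4 s hop), layer ablations, and temporal-response-function analysis.
6. **Onset detection** — a shared-temporal-weight sigmoid detector over
   first-differenced features (SGD, batch 200, learning rate 0.01,
   100 epochs) on 1 s segments, evaluated by ROC/AUROC against a
   tagging-posterior change baseline and the interobserver-agreement
   ceiling.
7. **Synthetic study generator** — seeded generators for audio scenes with
   planted events (WAV I/O included), response cohorts with configurable
   consensus, reaction times and lapse rates, embedding streams with
   planted change points, and linear ground-truth salience, so every stage
   can be validated against known structure.

## Worked example

```r
library(audsal)

# a synthetic cohort responding to two planted events
truth <- list(scene_id = "demo", planted_onsets = c(10, 28))
spec  <- response_spec(n_participants = 100, consensus = 0.6,
                       rt_median = 0.9, lapse_rate = 0.005)
trials <- make_response_set(truth, spec, trial_duration = 45, seed = 3)

map <- average_behavioral_salience(trials)
map
#> <salience_map> scene demo (fwd), 703 frames @ 64 ms, n = 100

events <- extract_events(map)
events[, c("onset", "offset", "slope", "consensus")]
#>    onset offset      slope consensus
#> 1  9.920 12.416 0.02009370 0.5672236
#> 2 27.904 30.400 0.01718336 0.4826662
```

The extracted onsets sit ≈0.1 s before the planted times: simulated
reaction times have a median of 0.9 s while the analysis shifts traces by
the standard 1 s adjustment. The consensus values recover the configured
responder fraction of 0.6 up to binomial sampling error
(SE ≈ 0.05 at n = 100). From here, `featurize()` and `layer_surprisal()`
produce the predictors, `fit_salience()` / `model_variants()` fit the
regression models, and `make_detection_dataset()` + `fit_detector()` +
`roc()` run the onset-detection analysis. `run_pipeline(experiment_config())`
executes the whole study end to end and writes every artifact with a
provenance record.

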