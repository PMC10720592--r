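# Shared fixtures, all generated in code.

# Smooth AR(1)-style feature streams on the 64 ms grid.
smooth_features <- function(n_frames, n_feat = 6L, seed = 1L, rho = 0.9) {
  set.seed(seed)
  v <- sapply(seq_len(n_feat), function(f) {
    x <- as.numeric(stats::filter(rnorm(n_frames), rho, "recursive"))
    x / sd(x)
  })
  feature_matrix(v, frame_step = 0.064)
}

# A salience map that steps from 0 to `level` at time t0 (unsmoothed).
step_map <- function(t0, level = 1, duration = 60, grid_step = 0.064,
                     scene_id = "s") {
  tt <- seq(0, duration - grid_step / 2, by = grid_step)
  salience_map(scene_id, ifelse(tt >= t0, level, 0), grid_step)
}

# Events data.frame helper.
ev_df <- function(onset, offset, scene_id = "s", direction = "fwd") {
  n <- length(onset)
  data.frame(scene_id = rep(scene_id, n), direction = rep(direction, n),
             onset = onset, offset = offset, slope = rep(0.01, n),
             consensus = rep(0.5, n), duration = offset - onset,
             closed_at_end = rep(FALSE, n))
}
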