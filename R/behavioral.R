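# Behavioral analysis: quality control, average behavioral salience maps,
# individual reaction times, and forward/backward agreement.

#' Construct a behavioral salience map
#'
#' The average behavioral salience is the across-participant mean of binary
#' attention-toward traces, reaction-time shifted and smoothed; values lie
#' in \[0, 1\] on a uniform time grid.
#'
#' @param scene_id Scene identifier.
#' @param values Numeric vector in \[0, 1\].
#' @param grid_step Grid step in seconds (default 0.064).
#' @param direction `"fwd"` or `"bwd"`.
#' @param n_participants Number of contributing participants.
#' @return Object of class `salience_map`.
#' @export
salience_map <- function(scene_id, values, grid_step = 0.064,
                         direction = "fwd", n_participants = NA_integer_) {
  values <- as.numeric(values)
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    stop("salience values must lie in [0, 1]")
  }
  structure(list(scene_id = as.character(scene_id), direction = direction,
                 grid_step = grid_step, values = pmin(pmax(values, 0), 1),
                 n_participants = n_participants),
            class = "salience_map")
}

#' @export
print.salience_map <- function(x, ...) {
  cat(sprintf("<salience_map> scene %s (%s), %d frames @ %.0f ms, n = %s\n",
              x$scene_id, x$direction, length(x$values), 1000 * x$grid_step,
              format(x$n_participants)))
  invisible(x)
}

# Time axis of a map (frame k covers [ (k-1), k ) * grid_step; times are
# frame left edges, the convention used throughout the pipeline).
map_time <- function(map) (seq_along(map$values) - 1L) * map$grid_step

#' Attention switching rate of one trial
#'
#' Number of 0/1 transitions in the binary trace divided by the trial
#' duration in seconds; the quality-control metric.
#'
#' @param trial A single trial (list with `t` and `attending`).
#' @return Switches per second.
#' @export
switching_rate <- function(trial) {
  att <- trial$attending
  if (length(att) < 1L) stop("empty trace")
  dur <- if (length(trial$t) > 1L) {
    diff(range(trial$t)) + (trial$t[2L] - trial$t[1L])
  } else 0
  if (dur <= 0) stop("zero-duration trace")
  sum(diff(att) != 0) / dur
}

#' Quality control of a trial cohort
#'
#' Percentile thresholds are computed over the switching rates of all
#' trials; trials strictly outside the open interval (lo percentile, hi
#' percentile) are flagged abnormal, and participants with more than
#' `max_abnormal` abnormal trials are excluded. With the open-bound rule, a
#' degenerate cohort where every rate is identical excludes no one.
#'
#' @param trials A `trial_set` covering all trials of the experiment.
#' @param hi_pct,lo_pct Percentile thresholds (defaults 90 and 10).
#' @param max_abnormal Exclusion threshold: participants are removed only
#'   when their abnormal-trial count strictly exceeds this (default 5).
#' @return A `qc_report`: list with per-trial `rates`, the thresholds, a
#'   per-participant table of abnormal counts, and `excluded` participant
#'   ids.
#' @export
quality_control <- function(trials, hi_pct = 90, lo_pct = 10, max_abnormal = 5L) {
  if (length(trials) < 2L) stop("need at least 2 trials for percentiles")
  rates <- vapply(trials, switching_rate, numeric(1))
  pid <- vapply(trials, function(x) x$participant_id, character(1))
  hi <- stats::quantile(rates, hi_pct / 100, names = FALSE)  # type 7: linear interp
  lo <- stats::quantile(rates, lo_pct / 100, names = FALSE)
  abnormal <- rates > hi | rates < lo
  counts <- tapply(abnormal, pid, sum)
  excluded <- names(counts)[counts > max_abnormal]
  structure(list(rates = rates, participant_id = pid,
                 hi = hi, lo = lo, abnormal = abnormal,
                 abnormal_counts = counts, excluded = excluded),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d trials, thresholds (%.3g, %.3g) sw/s, %d abnormal, %d participant(s) excluded\n",
              length(x$rates), x$lo, x$hi, sum(x$abnormal), length(x$excluded)))
  invisible(x)
}

# Drop trials of excluded participants.
apply_qc <- function(trials, qc) {
  keep <- vapply(trials, function(tr) !(tr$participant_id %in% qc$excluded),
                 logical(1))
  structure(trials[keep], class = "trial_set")
}

# Shift a trace earlier by `shift` seconds (tail padded by edge replication)
# and zero-order-hold resample it to the 64 ms analysis grid.
shift_and_resample <- function(trial, shift, grid_step, duration) {
  t_out <- seq(0, duration - grid_step / 2, by = grid_step)
  zoh_resample(trial$attending, trial$t - shift, t_out)
}

#' Average behavioral salience of one scene
#'
#' Each surviving trace is shifted earlier by `rt_shift` to undo the average
#' reaction-time delay, resampled to the analysis grid by zero-order hold,
#' averaged across participants, and smoothed with `smooth_passes`
#' applications of a centered moving average of duration `smooth_len`
#' (edges replicated).
#'
#' @param trials `trial_set` for one scene and direction.
#' @param rt_shift Reaction-time adjustment in seconds (default 1).
#' @param smooth_len Moving-average window in seconds (default 1.5).
#' @param smooth_passes Number of smoothing passes (default 3).
#' @param grid_step Analysis grid in seconds (default 0.064).
#' @return A [salience_map()].
#' @export
average_behavioral_salience <- function(trials, rt_shift = 1.0,
                                        smooth_len = 1.5, smooth_passes = 3L,
                                        grid_step = 0.064) {
  if (length(trials) < 1L) stop("need at least one trial")
  sid <- unique(vapply(trials, function(x) x$scene_id, character(1)))
  dir <- unique(vapply(trials, function(x) x$direction, character(1)))
  if (length(sid) != 1L) stop("mixed scene ids: ", paste(sid, collapse = ", "))
  if (length(dir) != 1L) stop("mixed directions")
  duration <- max(vapply(trials, function(x) max(x$t) + x$t[2L] - x$t[1L], numeric(1)))
  traces <- vapply(trials, shift_and_resample, numeric(length(seq(0, duration - grid_step / 2, by = grid_step))),
                   shift = rt_shift, grid_step = grid_step, duration = duration)
  avg <- rowMeans(traces)
  w <- odd_window(smooth_len, grid_step)
  sm <- box_smooth(avg, w, passes = smooth_passes)
  salience_map(scene_id = sid, values = sm, grid_step = grid_step,
               direction = dir, n_participants = length(trials))
}

#' Individual reaction times relative to salient-event onsets
#'
#' Traces are first shifted by `rt_shift` (the same adjustment used to build
#' the map). For each participant and event, the reaction time is the first
#' switch-toward (0 to 1) time within `onset +/- window` minus the onset;
#' events with no switch in the window are non-responsive. Per-participant
#' means are taken over responsive events only.
#'
#' @param trials `trial_set` for the scene.
#' @param events Event onsets in seconds, or a `salient_event` data.frame
#'   with an `onset` column.
#' @param window Half-width of the search window in seconds (default 1).
#' @param rt_shift Adjustment already applied to the map timeline (default 1).
#' @return data.frame with `participant_id`, `mean_rt`, `n_responsive`,
#'   `n_events`; `mean_rt` is `NA` for fully non-responsive participants.
#' @export
individual_reaction_times <- function(trials, events, window = 1.0,
                                      rt_shift = 1.0) {
  onsets <- if (is.data.frame(events)) events$onset else as.numeric(events)
  rows <- lapply(trials, function(tr) {
    t_sh <- tr$t - rt_shift
    sw <- which(diff(tr$attending) == 1L) + 1L   # first sample of attending
    t_sw <- t_sh[sw]
    rts <- vapply(onsets, function(on) {
      hit <- t_sw[t_sw >= on - window & t_sw <= on + window]
      if (length(hit)) hit[1L] - on else NA_real_
    }, numeric(1))
    data.frame(participant_id = tr$participant_id,
               mean_rt = if (all(is.na(rts))) NA_real_ else mean(rts, na.rm = TRUE),
               n_responsive = sum(!is.na(rts)), n_events = length(onsets))
  })
  do.call(rbind, rows)
}

#' Forward/backward agreement of salience maps
#'
#' The backward map is time-reversed onto the forward axis and the two maps
#' are compared with Spearman rank correlation.
#'
#' @param fwd_map,bwd_map [salience_map()]s for the same scene.
#' @param already_reversed Set `TRUE` if `bwd_map` is already on the forward
#'   time axis.
#' @return List with `rho`, `p_value`, and `n`.
#' @export
fwd_bwd_agreement <- function(fwd_map, bwd_map, already_reversed = FALSE) {
  if (fwd_map$scene_id != bwd_map$scene_id) {
    stop("maps are from different scenes")
  }
  if (abs(length(fwd_map$values) - length(bwd_map$values)) > 1L) {
    stop("map lengths differ by more than one grid step")
  }
  n <- min(length(fwd_map$values), length(bwd_map$values))
  a <- fwd_map$values[seq_len(n)]
  b <- bwd_map$values[seq_len(n)]
  if (!already_reversed) b <- rev(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, degenerate = FALSE)
}

#' Permutation noise floor for forward/backward agreement
#'
#' Repeatedly pairs each forward map with a backward map from a *different*
#' scene (derangement-style pairing) and summarises the resulting Spearman
#' correlations; the empirical chance level for [fwd_bwd_agreement()].
#' Degenerate (zero-variance) pairs are excluded and counted.
#'
#' @param fwd_maps,bwd_maps Lists of [salience_map()]s over the same scenes.
#' @param n_perm Number of shuffled pairings (default 100).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `rhos`, and `n_excluded`.
#' @export
noise_floor <- function(fwd_maps, bwd_maps, n_perm = 100L, seed = 1L) {
  ns <- length(fwd_maps)
  if (ns < 2L) stop("need at least 2 scenes for a shuffled noise floor")
  with_seed(seed, {
    rhos <- c(); excl <- 0L
    for (p in seq_len(n_perm)) {
      perm <- sample(ns)
      while (any(perm == seq_len(ns))) perm <- sample(ns)  # derangement
      for (i in seq_len(ns)) {
        f <- fwd_maps[[i]]; b <- bwd_maps[[perm[i]]]
        n <- min(length(f$values), length(b$values))
        a <- f$values[seq_len(n)]; bb <- rev(b$values[seq_len(n)])
        if (stats::sd(a) == 0 || stats::sd(bb) == 0) { excl <- excl + 1L; next }
        rhos <- c(rhos, stats::cor(a, bb, method = "spearman"))
      }
    }
    list(mean = mean(rhos), sd = stats::sd(rhos), rhos = rhos, n_excluded = excl)
  })
}

#' Write a salience map as a two-column CSV
#' @param map A [salience_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_salience_map <- function(map, path) {
  utils::write.csv(data.frame(t = map_time(map), value = map$values),
                   path, row.names = FALSE)
  invisible(path)
}
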