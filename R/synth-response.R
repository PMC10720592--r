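# Synthetic behavioral response cohorts for dichotic listening trials.
#
# The generator is the inverse of the behavioral analysis: given planted
# event onsets it draws, per participant and event, whether the participant
# responds (Bernoulli with the configured consensus), when (a shifted
# log-normal reaction time parameterised by its median and spread), and for
# how long (the hold duration), plus spurious lapse switches at a Poisson
# rate. Traces are binary attention-toward indicators sampled at a
# cursor-like rate (default 20 Hz).

#' Specify a synthetic response cohort
#'
#' @param n_participants Number of participants (> 0).
#' @param consensus Probability that a participant responds to an event;
#'   scalar or one value per planted event, each in \[0, 1\].
#' @param rt_median Median reaction time in seconds (>= 0).
#' @param rt_spread Reaction-time spread in seconds (standard-deviation-like
#'   scale of the log-normal; 0 gives identical reaction times).
#' @param lapse_rate Rate of spurious attention switches per second.
#' @param hold Attend duration after responding to an event, in seconds;
#'   `Inf` means the participant stays until the trial ends.
#' @param sample_rate_hz Cursor sampling rate of the raw traces (Hz).
#' @return Object of class `response_spec`.
#' @export
response_spec <- function(n_participants = 100L, consensus = 0.45,
                          rt_median = 0.9, rt_spread = 0.14,
                          lapse_rate = 0.005, hold = 2.5,
                          sample_rate_hz = 20) {
  if (n_participants < 1L) stop("`n_participants` must be positive")
  if (any(consensus < 0 | consensus > 1)) stop("`consensus` must be in [0, 1]")
  assert_scalar_num(rt_median, "rt_median", min = 0)
  assert_scalar_num(rt_spread, "rt_spread", min = 0)
  assert_scalar_num(lapse_rate, "lapse_rate", min = 0)
  structure(list(n_participants = as.integer(n_participants),
                 consensus = consensus, rt_median = rt_median,
                 rt_spread = rt_spread, lapse_rate = lapse_rate,
                 hold = hold, sample_rate_hz = sample_rate_hz),
            class = "response_spec")
}

# Shifted log-normal reaction times with the requested median and spread.
draw_rt <- function(n, median, spread) {
  if (spread <= 0) return(rep(median, n))
  sdlog <- sqrt(log1p((spread / max(median, 1e-6))^2))
  stats::rlnorm(n, meanlog = log(max(median, 1e-6)), sdlog = sdlog)
}

#' Simulate a set of trial responses for one scene
#'
#' @param truth Ground-truth record with `planted_onsets` (s), e.g. from
#'   [make_scene()], or a list with a `planted_onsets` field.
#' @param spec A [response_spec()].
#' @param trial_duration Trial length in seconds.
#' @param scene_id Scene identifier recorded in each trace.
#' @param direction `"fwd"` or `"bwd"`.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `trial_set`: list of per-participant traces, each a list with
#'   `participant_id`, `scene_id`, `direction`, `opposing_scene_id`, `t`
#'   (sample times, s) and `attending` (0/1).
#' @export
make_response_set <- function(truth, spec, trial_duration,
                              scene_id = truth$scene_id %||% "scene",
                              direction = "fwd", seed = 1L) {
  stopifnot(inherits(spec, "response_spec"))
  onsets <- truth$planted_onsets
  if (length(onsets) && any(onsets >= trial_duration)) {
    stop("planted onsets must lie within the trial duration")
  }
  fs <- spec$sample_rate_hz
  tt <- seq(0, trial_duration - 1 / fs, by = 1 / fs)
  cons <- rep_len(spec$consensus, length(onsets))
  with_seed(seed, {
    trials <- lapply(seq_len(spec$n_participants), function(p) {
      att <- rep(0L, length(tt))
      if (length(onsets)) {
        responds <- stats::runif(length(onsets)) < cons
        rts <- draw_rt(length(onsets), spec$rt_median, spec$rt_spread)
        for (j in which(responds)) {
          t_on <- onsets[j] + rts[j]
          t_off <- if (is.finite(spec$hold)) t_on + spec$hold else Inf
          att[tt >= t_on & tt < t_off] <- 1L
        }
      }
      if (spec$lapse_rate > 0) {
        n_lapse <- stats::rpois(1L, spec$lapse_rate * trial_duration)
        if (n_lapse > 0L) {
          t0 <- stats::runif(n_lapse, 0, trial_duration)
          w <- stats::runif(n_lapse, 0.1, 1)
          for (k in seq_len(n_lapse)) {
            seg <- tt >= t0[k] & tt < t0[k] + w[k]
            att[seg] <- 1L - att[seg]   # spurious switch then return
          }
        }
      }
      list(participant_id = sprintf("P%03d", p), scene_id = scene_id,
           direction = direction, opposing_scene_id = NA_character_,
           t = tt, attending = att)
    })
    structure(trials, class = "trial_set")
  })
}

#' Write a trial set as a long-format CSV trial log
#'
#' Columns: `participant_id, scene_id, direction, opposing_scene_id, t,
#' attending` (the schema shared with [read_trial_log()] and
#' [validate_trial_log()]).
#'
#' @param trials A `trial_set` (possibly concatenated across scenes).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  df <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(participant_id = tr$participant_id, scene_id = tr$scene_id,
               direction = tr$direction,
               opposing_scene_id = tr$opposing_scene_id %||% NA_character_,
               t = tr$t, attending = tr$attending)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial log CSV back into a trial set
#' @param path CSV path written by [write_trial_log()].
#' @return A `trial_set`.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$participant_id, df$scene_id, df$direction, drop = TRUE)
  trials <- lapply(split(df, key), function(d) {
    d <- d[order(d$t), ]
    list(participant_id = d$participant_id[1L], scene_id = d$scene_id[1L],
         direction = d$direction[1L],
         opposing_scene_id = d$opposing_scene_id[1L],
         t = d$t, attending = as.integer(d$attending))
  })
  names(trials) <- NULL
  structure(trials, class = "trial_set")
}
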