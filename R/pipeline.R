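# End-to-end workflow: configuration with the study's analysis constants,
# trial-log validation, and a deterministic synthetic-study pipeline that
# exercises every stage and writes its artifacts to a directory.

#' Experiment configuration
#'
#' Collects every analysis constant of the pipeline; defaults are the
#' values used throughout the behavioral and modeling stages (1 s
#' reaction-time shift, three 1.5 s smoothing passes, 90/10 switching-rate
#' percentiles with more-than-5 abnormal trials for exclusion, 50% event
#' overlap for matching, the 64 ms grid, 8 s / 4 s evaluation segments,
#' 0.5 s and 4 s context caps, 4 s surprisal past, 1 s detection segments
#' with 3 s context, SGD batch 200 / learning rate 0.01 / 100 epochs),
#' plus the synthetic-study scale parameters.
#'
#' @param ... Overrides for any configuration field.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    # analysis constants
    grid_step = 0.064, rt_shift = 1.0, smooth_len = 1.5, smooth_passes = 3L,
    hi_pct = 90, lo_pct = 10, max_abnormal = 5L, match_threshold = 0.5,
    min_slope = 1e-3, seg_len = 8, seg_hop = 4, seg_edge = 1,
    short_ctx = 0.5, long_ctx = 4, future_ctx = 1, surprisal_past = 4,
    lambda_a = 1, lambda_s = 1,
    det_seg = 1.024, det_past = 3, det_batch = 200L, det_lr = 0.01,
    det_epochs = 100L,
    # synthetic-study scale (the emulated study conditions)
    n_scenes = 20L, scene_duration = 120, n_participants = 100L,
    consensus = 0.45, rt_median = 0.9, rt_spread = 0.14, lapse_rate = 0.005,
    events_per_scene = 5L, event_duration = 2.5,
    bwd_drop_frac = 0.4, bwd_drop_factor = 0,
    n_layers = 4L, layer_dim = 8L, n_leaves = 15L,
    use_audio = FALSE, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "experiment_config")
}

#' Validate a trial-log CSV
#'
#' Schema and content checks for the trial-log interchange format: required
#' columns, binary attending values, strictly increasing time within each
#' trial, and duplicate-trial detection. Malformed rows are located, not
#' silently dropped.
#'
#' @param path CSV path.
#' @return List with `valid`, `errors` (located messages), `n_rows`,
#'   `n_participants`, `n_scenes`, `duplicates`.
#' @export
validate_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  errors <- character(0)
  need <- c("participant_id", "scene_id", "direction", "opposing_scene_id",
            "t", "attending")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    errors <- c(errors, paste("missing column(s):", paste(miss, collapse = ", ")))
  } else {
    bad_att <- which(!df$attending %in% c(0, 1))
    if (length(bad_att)) {
      errors <- c(errors, paste0("non-binary attending value at row(s): ",
                                 paste(utils::head(bad_att, 10L), collapse = ", ")))
    }
    bad_dir <- which(!df$direction %in% c("fwd", "bwd"))
    if (length(bad_dir)) {
      errors <- c(errors, paste0("direction must be fwd/bwd at row(s): ",
                                 paste(utils::head(bad_dir, 10L), collapse = ", ")))
    }
    key <- paste(df$participant_id, df$scene_id, df$direction)
    for (k in unique(key)) {
      tt <- df$t[key == k]
      if (is.unsorted(tt, strictly = TRUE)) {
        errors <- c(errors, paste0("non-monotone time within trial ", k))
      }
    }
  }
  dup <- character(0)
  if (!length(miss)) {
    cnt <- stats::aggregate(t ~ participant_id + scene_id + direction, df,
                            function(v) anyDuplicated(v) > 0)
    dup <- with(cnt, paste(participant_id, scene_id, direction)[t])
    if (length(dup)) errors <- c(errors, paste("duplicate trial samples for:",
                                               paste(dup, collapse = "; ")))
  }
  list(valid = length(errors) == 0L, errors = errors, n_rows = nrow(df),
       n_participants = if (length(miss)) NA else length(unique(df$participant_id)),
       n_scenes = if (length(miss)) NA else length(unique(df$scene_id)),
       duplicates = dup)
}

# Smooth synthetic acoustic-feature streams (AR-filtered noise) on the 64 ms
# grid, with level bumps at the planted onsets so features carry event
# information.
synthetic_feature_stream <- function(n_frames, onsets, grid_step, seed,
                                     n_features = 16L, bump = 2,
                                     names = NULL) {
  with_seed(seed, {
    v <- sapply(seq_len(n_features), function(f) {
      x <- as.numeric(stats::filter(stats::rnorm(n_frames), 0.9, "recursive"))
      x / stats::sd(x)
    })
    tt <- (seq_len(n_frames) - 1L) * grid_step
    for (on in onsets) {
      sel <- tt >= on & tt < on + 2
      v[sel, ] <- v[sel, , drop = FALSE] +
        matrix(bump * stats::runif(n_features), sum(sel), n_features, byrow = TRUE)
    }
    v
  })
}

#' Run the full synthetic study pipeline
#'
#' Generates a synthetic study at the configured scale (scenes, forward and
#' backward response cohorts, embedding streams and class posteriors),
#' then runs quality control, salience mapping, event extraction and
#' matching, feature and surprisal computation, the regression variants with
#' segment evaluation, and onset detection with the interobserver ceiling,
#' writing every artifact plus a provenance log to `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results: `maps`,
#'   `events`, `matches`, `variants`, `segments`, `detection`, and the
#'   provenance record.
#' @export
run_pipeline <- function(config = experiment_config(), out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- config$grid_step
  dur <- config$scene_duration
  n_frames <- as.integer(floor(dur / step))
  scenes <- sprintf("scene%02d", seq_len(config$n_scenes))
  maps <- list(fwd = list(), bwd = list())
  all_trials <- list(fwd = list(), bwd = list())
  onsets_by_scene <- list(); truths <- list()
  features <- list(); surprisals <- list(); posts <- list()

  for (i in seq_along(scenes)) {
    sid <- scenes[i]
    # planted onsets: jittered regular spacing inside [5, dur - 10] so
    # events stay separated regardless of the configured scene length
    sseed <- child_seed(config$seed, paste0("scene", i))
    k <- config$events_per_scene
    grid_pos <- seq(5, dur - 10, length.out = k + 1L)[seq_len(k)]
    gap <- if (k > 1L) diff(grid_pos)[1L] else (dur - 15)
    onsets <- sort(with_seed(sseed, grid_pos + stats::runif(k, 0, 0.4 * gap)))
    onsets_by_scene[[sid]] <- onsets
    truth_fwd <- list(scene_id = sid, planted_onsets = onsets)
    # in the reversed scene an event occupying [o, o + d] is audible from
    # dur - o - d onward, so backward listeners respond from there
    bwd_onsets <- dur - onsets - config$event_duration
    ord_bwd <- order(bwd_onsets)
    truth_bwd <- list(scene_id = sid, planted_onsets = bwd_onsets[ord_bwd])
    # a configurable fraction of events loses its consensus in one
    # direction only, emulating semantically driven (mismatch-prone)
    # events; the drops are split between the two directions
    k <- config$events_per_scene
    n_drop <- round(config$bwd_drop_frac * k)
    dropped <- with_seed(child_seed(config$seed, paste0("drop", i)),
                         sample(k, n_drop))
    drop_bwd <- dropped[seq_len(ceiling(n_drop / 2))]
    drop_fwd <- setdiff(dropped, drop_bwd)
    cons_fwd <- rep(config$consensus, k)
    cons_bwd <- cons_fwd
    cons_fwd[drop_fwd] <- cons_fwd[drop_fwd] * config$bwd_drop_factor
    cons_bwd[drop_bwd] <- cons_bwd[drop_bwd] * config$bwd_drop_factor
    cons_bwd <- cons_bwd[ord_bwd]
    rs <- function(cons) response_spec(n_participants = config$n_participants,
                                       consensus = cons,
                                       rt_median = config$rt_median,
                                       rt_spread = config$rt_spread,
                                       lapse_rate = config$lapse_rate)
    all_trials$fwd[[sid]] <- make_response_set(
      truth_fwd, rs(cons_fwd), dur, scene_id = sid, direction = "fwd",
      seed = child_seed(config$seed, paste0("fwd", i)))
    all_trials$bwd[[sid]] <- make_response_set(
      truth_bwd, rs(cons_bwd), dur, scene_id = sid, direction = "bwd",
      seed = child_seed(config$seed, paste0("bwd", i)))
    truths[[sid]] <- list(onsets = onsets, cons_fwd = cons_fwd,
                          bwd_onsets = truth_bwd$planted_onsets,
                          cons_bwd = cons_bwd)
    # acoustic features: real featurize on generated audio, or synthetic
    if (isTRUE(config$use_audio)) {
      ev <- data.frame(onset = onsets,
                       duration = pmin(config$event_duration, dur - onsets - 0.1),
                       kind = rep(c("tone", "noise_burst", "am_tone"),
                                  length.out = length(onsets)),
                       level_step = 15,
                       carrier = 300 * 2^seq_along(onsets), mod_rate = 8)
      sc <- make_scene(scene_spec(sid, dur, events = ev),
                       seed = child_seed(config$seed, paste0("wav", i)))
      features[[sid]] <- featurize(sc$waveform, sc$sample_rate, scene_id = sid)
    } else {
      v <- synthetic_feature_stream(n_frames, onsets, step,
                                    child_seed(config$seed, paste0("feat", i)))
      colnames(v) <- FEATURE_NAMES
      features[[sid]] <- feature_matrix(v, scene_id = sid, frame_step = step,
                                        zscore = TRUE)
    }
    nf_feat <- nrow(features[[sid]]$values)
    stream <- make_embedding_stream(
      nf_feat, layers = config$n_layers, dims = config$layer_dim,
      change_points = onsets[onsets / step < nf_feat - 1], step_norm = 3,
      frame_step = step, seed = child_seed(config$seed, paste0("emb", i)),
      scene_id = sid)
    surprisals[[sid]] <- layer_surprisal(stream, past = config$surprisal_past)
    # synthetic class posteriors: the active leaf switches at each onset
    leaves <- paste0(rep(c("H", "T", "M", "A", "B"),
                         length.out = config$n_leaves),
                     seq_len(config$n_leaves))
    pv <- matrix(0.05, nf_feat, config$n_leaves,
                 dimnames = list(NULL, leaves))
    seg_edges <- c(0, onsets, dur)
    tt <- (seq_len(nf_feat) - 1L) * step
    act <- with_seed(child_seed(config$seed, paste0("post", i)),
                     sample(config$n_leaves, length(seg_edges) - 1L,
                            replace = TRUE))
    for (s in seq_len(length(seg_edges) - 1L)) {
      pv[tt >= seg_edges[s] & tt < seg_edges[s + 1L], act[s]] <- 0.9
    }
    posts[[sid]] <- posterior_table(pv, synthetic_ontology(leaves), step)
  }

  # quality control over all trials of each experiment
  qc <- list()
  surviving <- list()
  for (d in c("fwd", "bwd")) {
    pool <- structure(do.call(c, all_trials[[d]]), class = "trial_set")
    qc[[d]] <- quality_control(pool, config$hi_pct, config$lo_pct,
                               config$max_abnormal)
    surviving[[d]] <- lapply(all_trials[[d]], apply_qc, qc = qc[[d]])
  }

  # salience maps and events
  events <- list(fwd = list(), bwd = list())
  matches <- list(fwd = list(), bwd = list())
  for (sid in scenes) {
    for (d in c("fwd", "bwd")) {
      maps[[d]][[sid]] <- average_behavioral_salience(
        surviving[[d]][[sid]], rt_shift = config$rt_shift,
        smooth_len = config$smooth_len, smooth_passes = config$smooth_passes,
        grid_step = step)
      events[[d]][[sid]] <- extract_events(maps[[d]][[sid]],
                                           min_slope = config$min_slope)
    }
    bwd_rev <- reverse_events(events$bwd[[sid]], dur)
    matches$fwd[[sid]] <- match_events(events$fwd[[sid]], bwd_rev,
                                       config$match_threshold)
    matches$bwd[[sid]] <- match_events(bwd_rev, events$fwd[[sid]],
                                       config$match_threshold)
  }
  all_slopes <- unlist(lapply(c(matches$fwd, matches$bwd), function(e) e$slope))
  matches$fwd <- lapply(matches$fwd, event_strength, all_slopes = all_slopes)
  matches$bwd <- lapply(matches$bwd, event_strength, all_slopes = all_slopes)

  # agreement and noise floor
  agree <- vapply(scenes, function(sid) {
    fwd_bwd_agreement(maps$fwd[[sid]], maps$bwd[[sid]])$rho
  }, numeric(1))
  nf <- if (length(scenes) >= 2L) {
    noise_floor(maps$fwd, maps$bwd, n_perm = 20L,
                seed = child_seed(config$seed, "floor"))
  } else list(mean = NA_real_, sd = NA_real_)

  # regression variants on the forward data; align target maps with frames
  for (sid in scenes) {   # align frame counts between features and maps
    n <- min(nrow(features[[sid]]$values), length(maps$fwd[[sid]]$values))
    features[[sid]]$values <- features[[sid]]$values[seq_len(n), , drop = FALSE]
    features[[sid]]$raw <- features[[sid]]$raw[seq_len(n), , drop = FALSE]
    surprisals[[sid]]$values <- surprisals[[sid]]$values[seq_len(n), , drop = FALSE]
  }
  targets <- lapply(scenes, function(sid) {
    m <- maps$fwd[[sid]]
    m$values <- m$values[seq_len(nrow(features[[sid]]$values))]
    m
  })
  names(targets) <- scenes
  variants <- model_variants(features, targets, surprisals,
                             lambda_a = config$lambda_a,
                             lambda_s = config$lambda_s,
                             short_ctx = config$short_ctx,
                             long_ctx = config$long_ctx,
                             future_ctx = config$future_ctx)
  seg_eval <- function(m, feats, surr) {
    evaluate_segments(m, feats, targets, surr, events = matches$fwd,
                      seg_len = config$seg_len, hop = config$seg_hop,
                      edge = config$seg_edge)
  }
  segments <- list(A_only = seg_eval(variants$A_only, features, NULL),
                   A_C = seg_eval(variants$A_C, features, NULL))
  if (!is.null(variants$A_S)) {
    segments$A_S <- seg_eval(variants$A_S, features, surprisals)
    surr_fm <- lapply(surprisals, function(s) {
      feature_matrix(s$values, scene_id = s$scene_id,
                     frame_step = s$frame_step,
                     names = paste0("S", seq_len(ncol(s$values))))
    })
    segments$S <- seg_eval(variants$S, surr_fm, NULL)
  }

  # detection on the forward data
  ds_list <- lapply(scenes, function(sid) {
    make_detection_dataset(features[[sid]], events$fwd[[sid]],
                           surprisal = surprisals[[sid]],
                           seg_s = config$det_seg, past_s = config$det_past)
  })
  dataset <- bind_detection_datasets(ds_list)
  det <- fit_detector(dataset, batch_size = config$det_batch,
                      learning_rate = config$det_lr,
                      epochs = config$det_epochs,
                      seed = child_seed(config$seed, "sgd"))
  det_roc <- roc(det, dataset = dataset)
  inter <- unlist(lapply(seq_along(scenes), function(i) {
    sid <- scenes[i]
    interobserver_signal(surviving$fwd[[sid]], ds_list[[i]]$starts,
                         ds_list[[i]]$seg_s, rt_shift = config$rt_shift)
  }))
  inter_roc <- roc(inter, dataset$y)
  post_rocs <- lapply(seq_along(scenes), function(i) {
    baseline_posterior_change(posts[[scenes[i]]], ds_list[[i]])$auroc
  })

  # ---- artifacts ----
  for (sid in scenes) {
    write_salience_map(maps$fwd[[sid]], file.path(out_dir, paste0(sid, "_fwd_map.csv")))
    write_salience_map(maps$bwd[[sid]], file.path(out_dir, paste0(sid, "_bwd_map.csv")))
    write_events(matches$fwd[[sid]], file.path(out_dir, paste0(sid, "_fwd_events.csv")))
    write_events(matches$bwd[[sid]], file.path(out_dir, paste0(sid, "_bwd_events.csv")))
    write_features(features[[sid]], file.path(out_dir, paste0(sid, "_features.csv")))
  }
  seg_df <- do.call(rbind, lapply(names(segments), function(v) {
    cbind(variant = v, as.data.frame(segments[[v]]))
  }))
  utils::write.csv(seg_df, file.path(out_dir, "segment_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(scene = scenes, spearman = agree),
                   file.path(out_dir, "fwd_bwd_agreement.csv"), row.names = FALSE)
  det_df <- data.frame(model = c("detector", "interobserver",
                                 paste0("posterior_", scenes)),
                       auroc = c(det_roc$auroc, inter_roc$auroc,
                                 unlist(post_rocs)))
  utils::write.csv(det_df, file.path(out_dir, "detection_auroc.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("audsal")),
               n_scenes = length(scenes),
               qc_excluded = lapply(qc, function(q) q$excluded))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(maps = maps, events = events, matches = matches,
                 agreement = agree, noise_floor = nf, qc = qc,
                 variants = variants, segments = segments,
                 detection = list(model = det, roc = det_roc,
                                  interobserver = inter_roc,
                                  posterior_auroc = unlist(post_rocs)),
                 features = features, surprisals = surprisals,
                 trials = surviving, datasets = ds_list, truths = truths,
                 provenance = prov))
}
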