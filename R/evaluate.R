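# Segment-wise model evaluation, scene-fold cross-validation, the four
# model variants (A-only, A-C, A-S, S), layer ablations, and class-wise
# performance breakdowns.

#' Segment a scene into overlapping evaluation windows
#'
#' 8 s segments with a 4 s hop, ignoring the first and last second of the
#' scene to avoid edge effects.
#'
#' @param duration Scene duration in seconds.
#' @param seg_len Segment length (s).
#' @param hop Hop (s).
#' @param edge Ignored margin at each end (s).
#' @return data.frame with `start`, `end`.
#' @keywords internal
make_segments <- function(duration, seg_len = 8, hop = 4, edge = 1) {
  starts <- seq(edge, duration - edge - seg_len, by = hop)
  if (!length(starts)) stop("scene too short for one evaluation segment")
  data.frame(start = starts, end = starts + seg_len)
}

# Overlap-based segment category: "match" / "mismatch" by larger overlap,
# "no-event" when no event intersects the segment.
segment_category <- function(start, end, events) {
  if (is.null(events) || nrow(events) == 0L) return("no-event")
  ov <- pmin(end, events$offset) - pmax(start, events$onset)
  ov[ov < 0] <- 0
  by_label <- tapply(ov, events$label, sum)
  if (all(by_label == 0)) return("no-event")
  names(by_label)[which.max(by_label)]
}

#' Segment-wise evaluation of a salience model
#'
#' Pearson correlation between the target salience and the model prediction
#' within each 8 s segment; segments are labeled match / mismatch /
#' no-event by their overlap with labeled events (larger total overlap wins
#' ties). Zero-variance segments are excluded and counted.
#'
#' @param model A fitted `salience_ridge`.
#' @param features,targets,surprisals Per-scene lists as in
#'   [fit_salience()].
#' @param events Optional per-scene list of matched event data.frames (with
#'   `onset`, `offset`, `label` columns from [match_events()]).
#' @param class_labels Optional per-scene function input: list of
#'   [posterior_table()]s; each segment then gets a dominant root class.
#' @param seg_len,hop,edge Segment geometry in seconds.
#' @return data.frame of class `segment_set`: `scene`, `start`, `end`, `r`,
#'   `category`, `root` (NA without posteriors), plus an `n_excluded`
#'   attribute.
#' @export
evaluate_segments <- function(model, features, targets, surprisals = NULL,
                              events = NULL, class_labels = NULL,
                              seg_len = 8, hop = 4, edge = 1) {
  if (inherits(features, "feature_matrix")) {
    features <- list(features); targets <- list(targets)
    if (!is.null(surprisals)) surprisals <- list(surprisals)
    if (!is.null(events)) events <- list(events)
    if (!is.null(class_labels)) class_labels <- list(class_labels)
  }
  preds <- predict(model, features, surprisals)
  rows_out <- list(); excluded <- 0L
  for (i in seq_along(features)) {
    fm <- features[[i]]
    tt <- (seq_len(nrow(fm$values)) - 1L) * fm$frame_step
    duration <- nrow(fm$values) * fm$frame_step
    segs <- make_segments(duration, seg_len, hop, edge)
    pr <- rep(NA_real_, nrow(fm$values))
    pr[preds[[i]]$rows] <- preds[[i]]$pred
    y <- targets[[i]]$values
    for (s in seq_len(nrow(segs))) {
      sel <- which(tt >= segs$start[s] & tt < segs$end[s] & !is.na(pr))
      if (length(sel) < 3L) { excluded <- excluded + 1L; next }
      ys <- y[sel]; ps <- pr[sel]
      if (stats::sd(ys) == 0 || stats::sd(ps) == 0) { excluded <- excluded + 1L; next }
      cat_s <- segment_category(segs$start[s], segs$end[s],
                                if (is.null(events)) NULL else events[[i]])
      root <- NA_character_
      if (!is.null(class_labels)) {
        root <- dominant_class(class_labels[[i]],
                               c(segs$start[s], segs$end[s]))$root
      }
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(scene = fm$scene_id, start = segs$start[s], end = segs$end[s],
                   r = stats::cor(ys, ps), category = cat_s, root = root)
    }
  }
  out <- do.call(rbind, rows_out)
  if (is.null(out)) out <- data.frame(scene = character(0), start = numeric(0),
                                      end = numeric(0), r = numeric(0),
                                      category = character(0), root = character(0))
  attr(out, "n_excluded") <- excluded
  class(out) <- c("segment_set", "data.frame")
  out
}

#' Compare segment correlations between groups
#'
#' Wilcoxon tests in the layout used for match/mismatch comparisons:
#' rank-sum for independent groups, sign-rank for paired model comparisons.
#'
#' @param segments `segment_set` data.frame.
#' @param by Column to group by (default `"category"`).
#' @param groups The two group labels to compare.
#' @param alternative Test sidedness.
#' @return List with the two group means and the rank-sum `p_value`.
#' @export
compare_segment_groups <- function(segments, by = "category",
                                   groups = c("match", "mismatch"),
                                   alternative = "two.sided") {
  x <- segments$r[segments[[by]] == groups[1L]]
  y <- segments$r[segments[[by]] == groups[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(mean_1 = mean(x), mean_2 = mean(y), p_value = NA_real_,
                skipped = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(mean_1 = mean(x), mean_2 = mean(y), p_value = wt$p.value, skipped = FALSE)
}

#' Scene-fold cross-validation over a hyperparameter grid
#'
#' Scenes are split into folds; for every grid point a model is trained on
#' all-but-one fold and scored by the mean held-out segment correlation;
#' the best grid point is refit on all scenes.
#'
#' @param features,targets,surprisals Per-scene lists.
#' @param grid data.frame of hyperparameters; recognised columns:
#'   `lambda_a`, `lambda_s`, `acoustic_past`, `acoustic_future`,
#'   `semantic_past`, `semantic_future`, `acoustic_smooth`,
#'   `semantic_smooth`. Missing columns use [context_design()] defaults.
#' @param n_folds Number of scene folds (default 10, capped at the scene
#'   count).
#' @param seed Seed for the fold assignment.
#' @return List with `best` (grid row), `scores` (mean held-out r per grid
#'   point), `fold_of` (fold per scene), and `model` (refit on all scenes).
#' @export
cross_validate <- function(features, targets, surprisals = NULL,
                           grid = data.frame(lambda_a = 10^seq(-4, 4, by = 2)),
                           n_folds = 10L, seed = 1L) {
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  ns <- length(features)
  n_folds <- min(n_folds, ns)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(n_folds), ns)))
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rs <- c()
    for (f in seq_len(n_folds)) {
      tr <- which(fold_of != f); te <- which(fold_of == f)
      m <- fit_grid_point(features[tr], targets[tr],
                          if (is.null(surprisals)) NULL else surprisals[tr],
                          grid[g, , drop = FALSE])
      seg <- evaluate_segments(m, features[te], targets[te],
                               if (is.null(surprisals)) NULL else surprisals[te])
      rs <- c(rs, seg$r)
    }
    scores[g] <- mean(rs)
  }
  best <- which.max(scores)
  model <- fit_grid_point(features, targets, surprisals,
                          grid[best, , drop = FALSE])
  list(best = grid[best, , drop = FALSE], scores = scores,
       fold_of = fold_of, model = model)
}

fit_grid_point <- function(features, targets, surprisals, row) {
  des <- context_design(
    acoustic_smooth = row$acoustic_smooth %||% 0.5,
    semantic_smooth = row$semantic_smooth %||% 1.0,
    acoustic_past = row$acoustic_past %||% 4.0,
    acoustic_future = row$acoustic_future %||% 1.0,
    semantic_past = row$semantic_past %||% 4.0,
    semantic_future = row$semantic_future %||% 1.0,
    frame_step = features[[1L]]$frame_step)
  fit_salience(features, targets, surprisals, design = des,
               lambda_a = row$lambda_a %||% 1, lambda_s = row$lambda_s %||% 1)
}

#' Fit the four standard model variants
#'
#' \describe{
#'   \item{A-only}{acoustic features, context capped at 0.5 s}
#'   \item{A-C}{acoustic features with long context (up to 4 s past)}
#'   \item{A-S}{acoustic long context plus semantic surprisal context}
#'   \item{S}{semantic surprisal context only}
#' }
#'
#' @param features,targets,surprisals Per-scene lists; `surprisals` are
#'   required for the A-S and S variants.
#' @param lambda_a,lambda_s Ridge penalties shared across variants.
#' @param short_ctx,long_ctx Context caps in seconds (defaults 0.5 and 4).
#' @param future_ctx Future context (s) for the long-context variants.
#' @param variants Which variants to fit; requesting `"A_S"` or `"S"`
#'   without surprisals is an error.
#' @return Named list of fitted `salience_ridge` models
#'   (`A_only`, `A_C`, and with surprisals `A_S`, `S`).
#' @export
model_variants <- function(features, targets, surprisals = NULL,
                           lambda_a = 1, lambda_s = 1,
                           short_ctx = 0.5, long_ctx = 4, future_ctx = 1,
                           variants = if (is.null(surprisals))
                             c("A_only", "A_C") else
                             c("A_only", "A_C", "A_S", "S")) {
  if (is.null(surprisals) && any(c("A_S", "S") %in% variants)) {
    stop("the A_S and S variants require surprisal input")
  }
  out <- list(
    A_only = fit_salience(features, targets, NULL,
                          design = context_design(acoustic_past = short_ctx,
                                                  acoustic_future = 0),
                          lambda_a = lambda_a),
    A_C = fit_salience(features, targets, NULL,
                       design = context_design(acoustic_past = long_ctx,
                                               acoustic_future = future_ctx),
                       lambda_a = lambda_a)
  )
  out <- out[intersect(c("A_only", "A_C"), variants)]
  if (!is.null(surprisals) && any(c("A_S", "S") %in% variants)) {
    out$A_S <- fit_salience(features, targets, surprisals,
                            design = context_design(acoustic_past = long_ctx,
                                                    acoustic_future = future_ctx,
                                                    semantic_past = long_ctx,
                                                    semantic_future = future_ctx),
                            lambda_a = lambda_a, lambda_s = lambda_s)
    # S model: semantic block only; realised as a zero-width acoustic block
    # is not possible, so we fit with the surprisal stream in the acoustic
    # slot of the design (a single-block ridge on surprisals).
    surr_fm <- lapply(surprisals, function(s) {
      feature_matrix(s$values, scene_id = s$scene_id, frame_step = s$frame_step,
                     names = paste0("S", seq_len(ncol(s$values))))
    })
    out$S <- fit_salience(surr_fm, targets, NULL,
                          design = context_design(acoustic_past = long_ctx,
                                                  acoustic_future = future_ctx),
                          lambda_a = lambda_s)
  }
  out[intersect(c("A_only", "A_C", "A_S", "S"), variants)]
}

#' Layer-ablation analysis of the semantic block
#'
#' Fits models that cumulatively include surprisal layers 1..l (cutoff 0 is
#' the acoustic-context model) and scores each by mean held-out segment
#' correlation on the supplied test scenes; a randomised baseline replaces
#' the added surprisals with white noise, averaged over `n_random` seeds.
#'
#' @param features,targets,surprisals Training lists.
#' @param test_features,test_targets,test_surprisals Held-out lists.
#' @param lambda_a,lambda_s Penalties.
#' @param n_random Random-baseline repetitions (default 10).
#' @param seed Baseline seed.
#' @return data.frame with `cutoff`, `r`, `r_random_mean`, `r_random_se`.
#' @export
layer_ablation <- function(features, targets, surprisals,
                           test_features, test_targets, test_surprisals,
                           lambda_a = 1, lambda_s = 1, n_random = 10L,
                           seed = 1L) {
  L <- ncol(surprisals[[1L]]$values)
  sub_surr <- function(ss, l, randomize = FALSE, rseed = 1L) {
    lapply(seq_along(ss), function(i) {
      v <- ss[[i]]$values[, seq_len(l), drop = FALSE]
      if (randomize) {
        v <- with_seed(rseed + i, matrix(stats::rnorm(length(v)), nrow(v)))
      }
      structure(list(values = v, warmup = ss[[i]]$warmup,
                     frame_step = ss[[i]]$frame_step,
                     scene_id = ss[[i]]$scene_id), class = "surprisal_matrix")
    })
  }
  rows <- lapply(0:L, function(l) {
    if (l == 0L) {
      m <- fit_salience(features, targets, NULL, lambda_a = lambda_a)
      r <- mean(evaluate_segments(m, test_features, test_targets)$r)
      return(data.frame(cutoff = 0L, r = r, r_random_mean = r, r_random_se = 0))
    }
    m <- fit_salience(features, targets, sub_surr(surprisals, l),
                      lambda_a = lambda_a, lambda_s = lambda_s)
    r <- mean(evaluate_segments(m, test_features, test_targets,
                                sub_surr(test_surprisals, l))$r)
    rr <- vapply(seq_len(n_random), function(k) {
      rs <- sub_surr(surprisals, l, randomize = TRUE,
                     rseed = child_seed(seed, paste0("abl", l, "_", k)))
      rst <- sub_surr(test_surprisals, l, randomize = TRUE,
                      rseed = child_seed(seed, paste0("ablt", l, "_", k)))
      mr <- fit_salience(features, targets, rs,
                         lambda_a = lambda_a, lambda_s = lambda_s)
      mean(evaluate_segments(mr, test_features, test_targets, rst)$r)
    }, numeric(1))
    data.frame(cutoff = l, r = r, r_random_mean = mean(rr),
               r_random_se = stats::sd(rr) / sqrt(n_random))
  })
  do.call(rbind, rows)
}

#' Class-wise performance of two models on labeled segments
#'
#' Per root class: mean segment correlation for each model and a one-sided
#' paired Wilcoxon sign-rank test that the second model improves on the
#' first. Classes with fewer than 2 segments are reported untested.
#'
#' @param seg_a,seg_b `segment_set`s from the two models over the *same*
#'   segments (same scenes and geometry), with `root` labels.
#' @return data.frame with `root`, `n`, `mean_r_a`, `mean_r_b`, `p_value`.
#' @export
classwise_performance <- function(seg_a, seg_b) {
  key_a <- paste(seg_a$scene, seg_a$start)
  key_b <- paste(seg_b$scene, seg_b$start)
  common <- intersect(key_a, key_b)
  a <- seg_a[match(common, key_a), ]
  b <- seg_b[match(common, key_b), ]
  rows <- lapply(split(seq_along(common), a$root), function(idx) {
    n <- length(idx)
    p <- if (n >= 2L) {
      suppressWarnings(stats::wilcox.test(b$r[idx], a$r[idx], paired = TRUE,
                                          alternative = "greater"))$p.value
    } else NA_real_
    data.frame(root = a$root[idx[1L]], n = n, mean_r_a = mean(a$r[idx]),
               mean_r_b = mean(b$r[idx]), p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
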