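# Salient-event extraction, attributes, time reversal, forward/backward
# matching, and group comparisons.

#' Extract salient events from a behavioral salience map
#'
#' The map derivative is the first-order difference of the salience values
#' (per frame). Event onsets are strict local maxima of the derivative that
#' exceed `min_slope`; each onset is paired with the next local minimum of
#' the derivative (events still open at the end of the scene are closed at
#' the scene end and flagged). Plateaus in the derivative are resolved by
#' letting the first sample of the plateau win. Per event:
#' \describe{
#'   \item{slope}{derivative value at the onset (salience units per frame)}
#'   \item{consensus}{maximum salience within \[onset, offset\]}
#'   \item{duration}{offset - onset, in seconds}
#' }
#' Strength is a corpus-level statistic; see [event_strength()].
#'
#' @param map A [salience_map()].
#' @param min_slope Minimum derivative value (per frame) for an onset to be
#'   considered; local maxima below this are treated as ripple.
#' @return data.frame of class `salient_event` with columns `scene_id`,
#'   `direction`, `onset`, `offset`, `slope`, `consensus`, `duration`,
#'   `closed_at_end`; zero rows for a constant map.
#' @export
extract_events <- function(map, min_slope = 1e-3) {
  v <- map$values
  if (length(v) < 3L) stop("map must have at least 3 samples")
  d <- diff(v)                       # derivative per frame, length T-1
  step <- map$grid_step
  empty <- data.frame(scene_id = character(0), direction = character(0),
                      onset = numeric(0), offset = numeric(0),
                      slope = numeric(0), consensus = numeric(0),
                      duration = numeric(0), closed_at_end = logical(0))
  class(empty) <- c("salient_event", "data.frame")
  n <- length(d)
  if (n < 3L || all(d == d[1L])) return(empty)
  maxima <- local_extrema(d, "max")
  maxima <- maxima[d[maxima] > min_slope]
  if (!length(maxima)) return(empty)
  minima <- local_extrema(d, "min")
  rows <- lapply(maxima, function(i) {
    nxt <- minima[minima > i]
    closed <- !length(nxt)
    j <- if (closed) n else nxt[1L]
    # derivative index i marks the rise between samples i and i+1; the onset
    # time is the left edge of that rise on the map grid
    onset <- (i - 1L) * step
    offset <- (j - 1L) * step
    cons <- max(v[i:(j + 1L)])
    data.frame(onset = onset, offset = offset, slope = d[i],
               consensus = cons, duration = offset - onset,
               closed_at_end = closed)
  })
  out <- do.call(rbind, rows)
  out <- out[out$duration > 0, , drop = FALSE]
  out <- cbind(scene_id = map$scene_id, direction = map$direction, out)
  out <- out[order(out$onset), ]
  rownames(out) <- NULL
  class(out) <- c("salient_event", "data.frame")
  out
}

# Indices of strict local extrema with first-of-plateau tie handling. The
# series is padded at the start so that a leading plateau which later falls
# counts as an extremum (a map that ramps from its very first sample still
# yields an onset); a trailing plateau never counts because no fall is seen.
# Values within `tol` are treated as equal so that floating-point ripple on
# analytically flat stretches does not spawn spurious extrema.
local_extrema <- function(x, which = c("max", "min"), tol = 1e-9) {
  which <- match.arg(which)
  if (which == "min") x <- -x
  x <- c(-Inf, x)
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L] + tol) {
      # scan plateau of (numerically) equal values
      j <- i
      while (j < n && abs(x[j + 1L] - x[i]) <= tol) j <- j + 1L
      if (j < n && x[j + 1L] < x[i] - tol) idx <- c(idx, i)  # first sample wins
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx - 1L   # undo the front padding
}

#' Event strength relative to a corpus of onset slopes
#'
#' Strength is the onset slope plus the absolute consensus scaled by the
#' 75th percentile of all onset slopes in the corpus:
#' `strength = slope + consensus * P75(all_slopes)`.
#'
#' @param events `salient_event` data.frame (any number of rows).
#' @param all_slopes Onset slopes pooled over all scenes of the corpus.
#' @return `events` with a `strength` column added.
#' @export
event_strength <- function(events, all_slopes) {
  if (!length(all_slopes)) {
    stop("corpus slopes are required before strengths can be computed")
  }
  p75 <- stats::quantile(all_slopes, 0.75, names = FALSE)
  events$strength <- events$slope + events$consensus * p75
  events
}

#' Map backward-scene events onto the forward time axis
#'
#' Onsets and offsets are reflected about the scene duration:
#' `new onset = duration - old offset`, `new offset = duration - old onset`.
#' The operation is an involution.
#'
#' @param events `salient_event` data.frame.
#' @param scene_duration Scene duration in seconds.
#' @return Reversed events, re-sorted by onset.
#' @export
reverse_events <- function(events, scene_duration) {
  if (nrow(events) == 0L) return(events)
  if (any(events$onset < 0) || any(events$offset > scene_duration + 1e-9)) {
    stop("events must lie within [0, scene_duration]")
  }
  on <- scene_duration - events$offset
  off <- scene_duration - events$onset
  events$onset <- on
  events$offset <- off
  events <- events[order(events$onset), ]
  rownames(events) <- NULL
  events
}

#' Match reference events against another event list by interval overlap
#'
#' For each reference event the maximum interval intersection with any event
#' of the other list is computed and normalised by the reference event's own
#' duration. Events whose overlap score strictly exceeds `threshold` are
#' labeled `"match"`, the rest `"mismatch"` (a score of exactly 0.5 at the
#' default threshold is a mismatch).
#'
#' @param ref_events Reference `salient_event` data.frame.
#' @param other_events Events already mapped onto the same time axis (use
#'   [reverse_events()] for backward scenes).
#' @param threshold Overlap fraction that must be exceeded (default 0.5).
#' @return `ref_events` with `best_overlap` (s), `overlap_score`, `label`.
#' @export
match_events <- function(ref_events, other_events, threshold = 0.5) {
  if (nrow(ref_events) == 0L) {
    ref_events$best_overlap <- numeric(0)
    ref_events$overlap_score <- numeric(0)
    ref_events$label <- character(0)
    return(ref_events)
  }
  if (any(ref_events$duration <= 0)) stop("zero-duration reference event")
  best <- vapply(seq_len(nrow(ref_events)), function(i) {
    a0 <- ref_events$onset[i]; a1 <- ref_events$offset[i]
    if (nrow(other_events) == 0L) return(0)
    ov <- pmin(a1, other_events$offset) - pmax(a0, other_events$onset)
    max(0, ov)
  }, numeric(1))
  ref_events$best_overlap <- best
  ref_events$overlap_score <- pmin(best / ref_events$duration, 1)
  ref_events$label <- ifelse(ref_events$overlap_score > threshold,
                             "match", "mismatch")
  ref_events
}

#' Compare event attributes between labeled groups
#'
#' Per attribute, group means and a two-sided Wilcoxon rank-sum test between
#' the two groups, in the layout used for matched-vs-mismatched event
#' comparisons.
#'
#' @param groups Named list of two `salient_event` data.frames (each with a
#'   `strength` column if `"strength"` is requested).
#' @param attributes Character vector among
#'   `c("duration", "strength", "slope", "consensus")`.
#' @return data.frame with one row per attribute: the two group means, the
#'   rank-sum statistic `W`, and `p_value` (`NA`, flagged, when a group has
#'   fewer than 2 events).
#' @export
compare_event_groups <- function(groups,
                                 attributes = c("duration", "strength",
                                                "slope", "consensus")) {
  if (length(groups) != 2L || is.null(names(groups))) {
    stop("`groups` must be a named list of two event sets")
  }
  g1 <- groups[[1L]]; g2 <- groups[[2L]]
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("each group must be non-empty")
  rows <- lapply(attributes, function(a) {
    x <- g1[[a]]; y <- g2[[a]]
    if (is.null(x) || is.null(y)) stop("attribute not present: ", a)
    skipped <- length(x) < 2L || length(y) < 2L
    if (!skipped) {
      wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
      W <- unname(wt$statistic); p <- wt$p.value
    } else {
      W <- NA_real_; p <- NA_real_
    }
    df <- data.frame(attribute = a, mean_1 = mean(x), mean_2 = mean(y),
                     W = W, p_value = p, skipped = skipped)
    names(df)[2:3] <- paste0("mean_", names(groups))
    df
  })
  do.call(rbind, rows)
}

#' Write salient events as CSV (times with 3-decimal precision)
#' @param events `salient_event` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- events
  for (cl in c("onset", "offset", "duration")) ev[[cl]] <- round(ev[[cl]], 3)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
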