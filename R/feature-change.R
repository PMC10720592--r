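# Feature-change analysis around salient-event onsets: the difference
# between the average feature in the half-second window 0.5-1.0 s after the
# onset and the matching window before it, with one-sample t-tests, a
# factorial ANOVA over presentation / event type / feature, and
# Tukey-corrected pairwise contrasts.

#' Feature changes around event onsets
#'
#' For each onset with full window support, `delta = mean(feature in
#' [onset+0.5, onset+1.0]) - mean(feature in [onset-1.0, onset-0.5])`, per
#' feature. Onsets without full support are excluded and counted.
#'
#' @param features A `feature_matrix`.
#' @param onsets Event onsets in seconds (or a `salient_event` data.frame).
#' @param pre_win,post_win Window bounds relative to the onset, in seconds.
#' @return List of class `feature_change_table`: `delta` (events x
#'   features), `onsets` (those used), `n_excluded`.
#' @export
feature_change <- function(features, onsets,
                           pre_win = c(-1.0, -0.5), post_win = c(0.5, 1.0)) {
  if (is.data.frame(onsets)) onsets <- onsets$onset
  x <- features$values
  tt <- (seq_len(nrow(x)) - 1L) * features$frame_step
  if (!length(onsets)) {
    return(structure(list(delta = matrix(0, 0, ncol(x),
                                         dimnames = list(NULL, features$names)),
                          onsets = numeric(0), n_excluded = 0L),
                     class = "feature_change_table"))
  }
  # window means are exact averages of the piecewise-linear interpolant of
  # the frame samples, so linear trends give closed-form changes; the
  # cumulative trapezoid integral is computed once per feature
  n <- nrow(x)
  ct <- rbind(0, apply((x[-1L, , drop = FALSE] + x[-n, , drop = FALSE]) / 2 *
                         diff(tt), 2L, cumsum))
  integral_at <- function(t) {       # vector over features
    k <- findInterval(t, tt)
    k <- min(max(k, 1L), n - 1L)
    frac <- (t - tt[k]) / (tt[k + 1L] - tt[k])
    xt <- x[k, ] + frac * (x[k + 1L, ] - x[k, ])
    ct[k, ] + (x[k, ] + xt) / 2 * (t - tt[k])
  }
  win_mean <- function(a, b) (integral_at(b) - integral_at(a)) / (b - a)
  rows <- list(); used <- numeric(0); excluded <- 0L
  for (on in onsets) {
    if (on + pre_win[1L] < tt[1L] - 1e-9 ||
        on + post_win[2L] > tt[n] + 1e-9) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <-
      win_mean(on + post_win[1L], on + post_win[2L]) -
      win_mean(on + pre_win[1L], on + pre_win[2L])
    used <- c(used, on)
  }
  delta <- do.call(rbind, rows)
  if (is.null(delta)) delta <- matrix(0, 0, ncol(x))
  colnames(delta) <- features$names
  structure(list(delta = delta, onsets = used, n_excluded = excluded),
            class = "feature_change_table")
}

#' Statistical tests on feature-change tables
#'
#' Takes a long-format table of per-event feature changes with grouping
#' columns and computes (i) per (group, feature) one-sample t-tests of the
#' change against zero, (ii) a factorial ANOVA of the change on presentation
#' direction, event type and feature (main effects plus all two-way
#' interactions), and (iii) per-feature pairwise group contrasts with
#' Tukey HSD correction.
#'
#' @param long data.frame with columns `delta`, `feature`, `presentation`
#'   (fwd/bwd), `event_type` (match/mismatch). Build it with
#'   [feature_change_long()].
#' @return List with `t_tests` (data.frame), `anova` (the aov summary table
#'   as a data.frame), `pairwise` (per-feature Tukey HSD contrasts).
#' @export
feature_change_tests <- function(long) {
  need <- c("delta", "feature", "presentation", "event_type")
  if (!all(need %in% names(long))) {
    stop("`long` must have columns ", paste(need, collapse = ", "))
  }
  long$feature <- factor(long$feature)
  long$presentation <- factor(long$presentation)
  long$event_type <- factor(long$event_type)
  cells <- table(long$presentation, long$event_type)
  if (any(cells == 0)) {
    stop("empty presentation x event_type cell; ANOVA needs every cell populated")
  }
  small <- stats::aggregate(delta ~ presentation + event_type + feature,
                            long, length)
  if (any(small$delta < 2)) {
    stop("every (presentation, event type, feature) cell needs >= 2 observations")
  }
  # (i) one-sample t per (presentation, event type, feature)
  t_tests <- do.call(rbind, lapply(
    split(long, list(long$presentation, long$event_type, long$feature)),
    function(d) {
      if (stats::sd(d$delta) == 0) {
        # degenerate: constant changes; zero mean is exactly null
        tval <- if (mean(d$delta) == 0) 0 else sign(mean(d$delta)) * Inf
        tt <- list(statistic = tval, parameter = length(d$delta) - 1L,
                   p.value = if (tval == 0) 1 else 0)
      } else {
        tt <- stats::t.test(d$delta, mu = 0)
      }
      data.frame(presentation = d$presentation[1L], event_type = d$event_type[1L],
                 feature = d$feature[1L], mean_delta = mean(d$delta),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
    }))
  rownames(t_tests) <- NULL
  # (ii) factorial ANOVA with two-way interactions
  fit <- stats::aov(delta ~ presentation + event_type + feature +
                      presentation:event_type + presentation:feature +
                      event_type:feature, data = long)
  an <- as.data.frame(summary(fit)[[1L]])
  an$term <- trimws(rownames(an))
  rownames(an) <- NULL
  names(an) <- c("df", "sum_sq", "mean_sq", "F", "p_value", "term")
  # (iii) per-feature pairwise contrasts of the four groups, Tukey-corrected
  long$group <- interaction(long$presentation, long$event_type, sep = "-")
  pairwise <- lapply(split(long, long$feature), function(d) {
    if (nlevels(droplevels(d$group)) < 2L) return(NULL)
    hsd <- stats::TukeyHSD(stats::aov(delta ~ group, data = droplevels(d)))
    out <- as.data.frame(hsd$group)
    out$contrast <- rownames(out)
    rownames(out) <- NULL
    out
  })
  list(t_tests = t_tests, anova = an, pairwise = pairwise)
}

#' Assemble a long-format feature-change table
#'
#' @param tables Named list of `feature_change_table`s; names are
#'   `"<presentation>-<event_type>"`, e.g. `"fwd-match"`.
#' @return data.frame with columns `delta`, `feature`, `presentation`,
#'   `event_type`, `event` suitable for [feature_change_tests()].
#' @export
feature_change_long <- function(tables) {
  rows <- lapply(names(tables), function(nm) {
    parts <- strsplit(nm, "-", fixed = TRUE)[[1L]]
    d <- tables[[nm]]$delta
    if (!nrow(d)) return(NULL)
    data.frame(delta = as.numeric(d),
               feature = rep(colnames(d), each = nrow(d)),
               presentation = parts[1L], event_type = parts[2L],
               event = rep(seq_len(nrow(d)), times = ncol(d)))
  })
  do.call(rbind, rows)
}
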