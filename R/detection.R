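# Salient-event-onset detection: labeled 1 s segments over first-differenced
# features, a shared-temporal-weight sigmoid detector trained by minibatch
# SGD with cross-entropy, ROC/AUROC evaluation, the tagging-posterior
# change baseline, and the interobserver ceiling.

#' Build a labeled detection dataset from feature streams
#'
#' Features are first-differenced, then cut into non-overlapping segments of
#' about 1 s (16 frames at 64 ms); a segment is positive iff at least one
#' event onset falls in its half-open interval `[start, start+len)`. For the
#' A-S variant a past context of 3 s is appended in front of each segment
#' and the semantic surprisals are stacked below the acoustic features.
#'
#' @param features A `feature_matrix`.
#' @param events Event onsets in seconds (or a `salient_event` data.frame).
#' @param surprisal Optional `surprisal_matrix`; its presence selects the
#'   A-S windowing (3 s past context).
#' @param seg_s Segment length in seconds (default 1.024 = 16 frames).
#' @param past_s Past context for the A-S variant (default 3).
#' @param standardize Z-score each first-differenced feature channel over
#'   the scene before windowing (stabilises the SGD training when channels
#'   live on very different scales).
#' @return List of class `detection_dataset`: `x` (array segments x
#'   features x window frames), `y` (0/1), `starts` (s), `variant`.
#' @export
make_detection_dataset <- function(features, events, surprisal = NULL,
                                   seg_s = 1.024, past_s = 3,
                                   standardize = TRUE) {
  onsets <- if (is.data.frame(events)) events$onset else as.numeric(events)
  step <- features$frame_step
  xa <- t(as.matrix(features$values))          # features x T
  if (!is.null(surprisal)) {
    if (ncol(xa) != nrow(surprisal$values)) stop("frame count mismatch")
    xa <- rbind(xa, t(as.matrix(surprisal$values)))
  }
  dx <- cbind(0, t(diff(t(xa))))               # first difference along time
  if (standardize) dx <- t(zscore_cols(t(dx), warn = FALSE))
  Tn <- ncol(dx)
  seg_f <- as.integer(round(seg_s / step))
  ctx_f <- if (is.null(surprisal)) 0L else as.integer(round(past_s / step))
  if (Tn < seg_f + ctx_f) stop("scene shorter than one segment plus context")
  win <- seg_f + ctx_f
  starts <- seq(ctx_f, Tn - seg_f, by = seg_f)  # frame index of segment start
  n_seg <- length(starts)
  x <- array(0, dim = c(n_seg, nrow(dx), win))
  y <- integer(n_seg)
  t_start <- starts * step
  for (s in seq_len(n_seg)) {
    idx <- (starts[s] - ctx_f + 1L):(starts[s] + seg_f)
    x[s, , ] <- dx[, idx]
    y[s] <- as.integer(any(onsets >= t_start[s] & onsets < t_start[s] + seg_f * step))
  }
  structure(list(x = x, y = y, starts = t_start, seg_s = seg_f * step,
                 variant = if (is.null(surprisal)) "A" else "A-S"),
            class = "detection_dataset")
}

#' Concatenate detection datasets across scenes
#' @param ... `detection_dataset`s of the same variant and geometry.
#' @return A combined `detection_dataset` (the `starts` are kept per input
#'   in a `scene` index).
#' @export
bind_detection_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1L]], "detection_dataset")) ds <- ds[[1L]]
  v <- unique(vapply(ds, function(d) d$variant, character(1)))
  if (length(v) != 1L) stop("mixed detector variants")
  x <- do.call(abind_first, lapply(ds, function(d) d$x))
  structure(list(x = x, y = unlist(lapply(ds, function(d) d$y)),
                 starts = unlist(lapply(ds, function(d) d$starts)),
                 scene = rep(seq_along(ds), vapply(ds, function(d) length(d$y), integer(1))),
                 seg_s = ds[[1L]]$seg_s, variant = v),
            class = "detection_dataset")
}

# rbind for the first dimension of 3-d arrays.
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1L], integer(1))),
                          d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1L]
    out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit the salient-event-onset detector
#'
#' A bilinear logistic model with temporal weights shared across features:
#' for a segment `X` (features x window frames) the detection score is
#' `sigmoid(v' X u + b)` with one temporal weight vector `u` over the
#' window and per-feature combination weights `v`. Trained by plain
#' minibatch stochastic gradient descent on the cross-entropy loss
#' (batch 200, learning rate 0.01, 100 epochs); the epoch snapshot with the
#' lowest full-training loss is returned.
#'
#' @param dataset A `detection_dataset` with both classes present.
#' @param batch_size,learning_rate,epochs SGD hyperparameters.
#' @param seed Seed controlling initialisation and shuffling.
#' @param n_restarts Independent random initialisations; the bilinear loss
#'   is non-convex, so the restart reaching the lowest training loss wins.
#' @return Object of class `salience_detector` with `v`, `u`, `b`,
#'   `variant`, `loss` (per epoch), `best_epoch`.
#' @export
fit_detector <- function(dataset, batch_size = 200L, learning_rate = 0.01,
                         epochs = 100L, seed = 1L, n_restarts = 3L) {
  fits <- lapply(seq_len(n_restarts), function(rs) {
    fit_detector_once(dataset, batch_size, learning_rate, epochs,
                      seed = child_seed(seed, paste0("restart", rs)))
  })
  fits[[which.min(vapply(fits, function(f) f$best_loss, numeric(1)))]]
}

fit_detector_once <- function(dataset, batch_size, learning_rate, epochs,
                              seed) {
  y <- dataset$y
  if (length(unique(y)) < 2L) stop("both classes must be present to train")
  x <- dataset$x
  n <- dim(x)[1L]; nf <- dim(x)[2L]; nw <- dim(x)[3L]
  with_seed(seed, {
    v <- stats::rnorm(nf, sd = 0.1)
    u <- stats::rnorm(nw, sd = 0.1)
    b <- 0
    best <- list(loss = Inf)
    losses <- numeric(epochs)
    score_all <- function(v, u, b) {
      vX <- apply(x, 3L, function(sl) sl %*% v)     # n x nw
      sigmoid(as.numeric(vX %*% u) + b)
    }
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , , drop = FALSE]
        m <- length(idx)
        vX <- apply(xb, 3L, function(sl) sl %*% v)       # m x nw
        if (m == 1L) vX <- matrix(vX, nrow = 1L)
        Xu <- apply(xb, 2L, function(sl) {
          if (m == 1L) sum(sl * u) else sl %*% u
        })                                               # m x nf
        if (m == 1L) Xu <- matrix(Xu, nrow = 1L)
        p <- sigmoid(as.numeric(vX %*% u) + b)
        e <- p - y[idx]
        gv <- as.numeric(crossprod(Xu, e)) / m
        gu <- as.numeric(crossprod(vX, e)) / m
        gb <- mean(e)
        v <- v - learning_rate * gv
        u <- u - learning_rate * gu
        b <- b - learning_rate * gb
      }
      p_all <- score_all(v, u, b)
      eps <- 1e-12
      losses[ep] <- -mean(y * log(p_all + eps) + (1 - y) * log(1 - p_all + eps))
      if (losses[ep] < best$loss) {
        best <- list(v = v, u = u, b = b, loss = losses[ep], epoch = ep)
      }
    }
    structure(list(v = best$v, u = best$u, b = best$b,
                   variant = dataset$variant, loss = losses,
                   best_epoch = best$epoch, best_loss = best$loss),
              class = "salience_detector")
  })
}

#' @export
print.salience_detector <- function(x, ...) {
  cat(sprintf("<salience_detector> variant %s: %d feature weights x %d temporal weights\n",
              x$variant, length(x$v), length(x$u)))
  cat(sprintf("  best training cross-entropy %.4f at epoch %d/%d\n",
              x$best_loss, x$best_epoch, length(x$loss)))
  invisible(x)
}

#' Detection scores of a fitted detector
#' @param object A `salience_detector`.
#' @param dataset A `detection_dataset` with matching geometry.
#' @param ... Unused.
#' @return Sigmoid scores in (0, 1), one per segment.
#' @export
predict.salience_detector <- function(object, dataset, ...) {
  x <- dataset$x
  vX <- apply(x, 3L, function(sl) sl %*% object$v)
  if (dim(x)[1L] == 1L) vX <- matrix(vX, nrow = 1L)
  sigmoid(as.numeric(vX %*% object$u) + object$b)
}

#' ROC curve and AUROC for a detection signal
#'
#' Sweeps thresholds over the unique scores, computes hit and false-alarm
#' rates, and integrates the curve by the trapezoidal rule. Equivalent to
#' the rank-based (Mann-Whitney) definition of the AUROC, which serves as
#' the independent cross-check in the test-suite.
#'
#' @param scores Numeric scores (higher = more likely an onset); or a
#'   `salience_detector` together with `dataset`.
#' @param labels 0/1 labels (ignored when `scores` is a detector).
#' @param dataset Needed when `scores` is a detector.
#' @return Object of class `roc_result`: `thresholds`, `hit`, `fa`,
#'   `auroc`.
#' @export
roc <- function(scores, labels = NULL, dataset = NULL) {
  if (inherits(scores, "salience_detector")) {
    if (is.null(dataset)) stop("`dataset` required with a detector")
    labels <- dataset$y
    scores <- predict(scores, dataset)
  }
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stop("need at least one positive and one negative")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  hit <- vapply(thr, function(th) sum(scores >= th & labels == 1L) / np, numeric(1))
  fa <- vapply(thr, function(th) sum(scores >= th & labels == 0L) / nn, numeric(1))
  auroc <- sum(diff(fa) * (utils::head(hit, -1L) + utils::tail(hit, -1L)) / 2)
  structure(list(thresholds = thr, hit = hit, fa = fa, auroc = auroc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUROC = %.3f\n",
              length(x$thresholds), x$auroc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fa, x$hit, type = "l", xlab = "false-alarm rate",
                 ylab = "hit rate", main = sprintf("ROC (AUROC %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Interobserver agreement detection signal
#'
#' Counts, per detection segment, the participants whose trace switches
#' toward the scene (0 to 1 transition) within the segment; the empirical
#' ceiling for detector performance. Traces are shifted by `rt_shift` so
#' the counts live on the same adjusted timeline as the event onsets.
#'
#' @param trials Quality-controlled `trial_set` for the scene.
#' @param starts Segment start times (s).
#' @param seg_s Segment length (s).
#' @param rt_shift Reaction-time adjustment (default 1).
#' @return Integer counts per segment (0..n participants).
#' @export
interobserver_signal <- function(trials, starts, seg_s, rt_shift = 1.0) {
  vapply(starts, function(t0) {
    sum(vapply(trials, function(tr) {
      sw <- which(diff(tr$attending) == 1L) + 1L
      t_sw <- tr$t[sw] - rt_shift
      any(t_sw >= t0 & t_sw < t0 + seg_s)
    }, logical(1)))
  }, numeric(1))
}

#' Tagging-posterior change baseline as an ROC result
#'
#' Max-pools the [posterior_change_signal()] within each detection segment
#' and evaluates it against the segment labels.
#'
#' @param post A [posterior_table()].
#' @param dataset A `detection_dataset` supplying segment starts and labels.
#' @param threshold,median_win Passed to [posterior_change_signal()].
#' @return An `roc_result`.
#' @export
baseline_posterior_change <- function(post, dataset, threshold = 0.5,
                                      median_win = 1.0) {
  sig <- posterior_change_signal(post, threshold, median_win)
  tt <- (seq_along(sig) - 1L) * post$frame_step
  scores <- vapply(dataset$starts, function(t0) {
    sel <- tt >= t0 & tt < t0 + dataset$seg_s
    if (any(sel)) max(sig[sel]) else 0
  }, numeric(1))
  roc(scores, dataset$y)
}
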