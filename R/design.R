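# Temporal-context design matrices: per-block moving-average smoothing and
# past/future lagging of acoustic and semantic feature streams on the
# shared 64 ms grid.

#' Specify the temporal-context design
#'
#' @param acoustic_smooth,semantic_smooth Moving-average smoothing lengths
#'   in seconds applied per block before lagging (0 disables).
#' @param acoustic_past,acoustic_future Context lengths in seconds for the
#'   acoustic block.
#' @param semantic_past,semantic_future Context lengths for the semantic
#'   block.
#' @param frame_step Grid step in seconds.
#' @return Object of class `context_design`.
#' @export
context_design <- function(acoustic_smooth = 0.5, semantic_smooth = 1.0,
                           acoustic_past = 4.0, acoustic_future = 1.0,
                           semantic_past = 4.0, semantic_future = 1.0,
                           frame_step = 0.064) {
  for (v in c(acoustic_past, acoustic_future, semantic_past, semantic_future)) {
    if (v < 0) stop("context lengths must be >= 0")
  }
  structure(list(acoustic_smooth = acoustic_smooth,
                 semantic_smooth = semantic_smooth,
                 acoustic_past = acoustic_past,
                 acoustic_future = acoustic_future,
                 semantic_past = semantic_past,
                 semantic_future = semantic_future,
                 frame_step = frame_step),
            class = "context_design")
}

# Lag a T x F matrix into a T x (F * n_lags) matrix; lags run from
# -n_future (lead) to +n_past (lag). Rows lacking full context are kept but
# reported via the returned `valid` mask.
lag_block <- function(x, n_past, n_future) {
  Tn <- nrow(x); Fk <- ncol(x)
  lags <- seq(-n_future, n_past)
  out <- matrix(0, Tn, Fk * length(lags))
  cn <- character(Fk * length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]
    src <- seq_len(Tn) - k
    ok <- src >= 1L & src <= Tn
    cols <- (li - 1L) * Fk + seq_len(Fk)
    out[ok, cols] <- x[src[ok], , drop = FALSE]
    cn[cols] <- paste0(colnames(x) %||% paste0("F", seq_len(Fk)), "_lag", k)
  }
  colnames(out) <- cn
  valid <- (seq_len(Tn) + n_future) <= Tn & (seq_len(Tn) - n_past) >= 1L
  list(x = out, valid = valid, lags = lags)
}

#' Build the lagged regression design for one scene
#'
#' Per block (acoustic, optional semantic): moving-average smoothing, then
#' past/future lagging, then column-wise concatenation. Frames lacking the
#' full context window are dropped; their indices are returned so targets
#' can be aligned.
#'
#' @param features A `feature_matrix` (acoustic block).
#' @param surprisal Optional `surprisal_matrix` (semantic block), or `NULL`.
#' @param design A [context_design()].
#' @return List with `X` (design matrix over valid frames), `rows` (kept
#'   frame indices), `blocks` (column index list per block), `lags_a`,
#'   `lags_s`.
#' @export
build_design <- function(features, surprisal = NULL, design = context_design()) {
  step <- design$frame_step
  xa <- as.matrix(features$values)
  Tn <- nrow(xa)
  np_a <- as.integer(round(design$acoustic_past / step))
  nf_a <- as.integer(round(design$acoustic_future / step))
  if (np_a + nf_a >= Tn) stop("acoustic context longer than the scene")
  if (design$acoustic_smooth > 0) {
    w <- odd_window(design$acoustic_smooth, step)
    xa <- apply(xa, 2L, box_smooth, width = w)
  }
  la <- lag_block(xa, np_a, nf_a)
  X <- la$x
  valid <- la$valid
  blocks <- list(acoustic = seq_len(ncol(la$x)))
  lags_s <- NULL
  if (!is.null(surprisal)) {
    xs <- as.matrix(surprisal$values)
    if (nrow(xs) != Tn) stop("feature and surprisal frame counts differ")
    np_s <- as.integer(round(design$semantic_past / step))
    nf_s <- as.integer(round(design$semantic_future / step))
    if (np_s + nf_s >= Tn) stop("semantic context longer than the scene")
    if (design$semantic_smooth > 0) {
      w <- odd_window(design$semantic_smooth, step)
      xs <- apply(xs, 2L, box_smooth, width = w)
    }
    colnames(xs) <- paste0("S", seq_len(ncol(xs)))
    ls <- lag_block(xs, np_s, nf_s)
    blocks$semantic <- ncol(X) + seq_len(ncol(ls$x))
    X <- cbind(X, ls$x)
    valid <- valid & ls$valid
    lags_s <- ls$lags
  }
  rows <- which(valid)
  list(X = X[rows, , drop = FALSE], rows = rows, blocks = blocks,
       lags_a = la$lags, lags_s = lags_s)
}
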