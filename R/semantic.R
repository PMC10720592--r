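# Semantic analysis: layer-wise surprisal of embedding streams, dominant
# root-class labeling via ontology belief propagation, and the
# tagging-posterior change-detection baseline.

#' Layer-wise surprisal of an embedding stream
#'
#' Surprisal of layer `l` at frame `t` is the Euclidean distance between the
#' layer output and the mean output over the preceding `past` seconds
#' (strictly past: frames `t-W .. t-1`). Warm-up frames with fewer than `W`
#' history frames use the history available and are flagged.
#'
#' @param stream An `embedding_stream` (see [make_embedding_stream()] or
#'   [as_embedding_stream()]).
#' @param past Past-context length in seconds (default 4).
#' @return A `surprisal_matrix`: list with `values` (T x L, non-negative;
#'   the first frame has no history and is set to 0), `warmup` (logical per
#'   frame), `frame_step`, `scene_id`.
#' @export
layer_surprisal <- function(stream, past = 4.0) {
  W <- as.integer(round(past / stream$frame_step))
  if (W < 2L) stop("`past` must cover at least 2 frames")
  Tn <- nrow(stream$layers[[1L]])
  if (Tn <= 1L) stop("stream must have more than one frame")
  vals <- sapply(stream$layers, function(y) {
    cs <- apply(y, 2L, cumsum)                  # running sums per dimension
    s <- rep(0, Tn)                             # frame 1 has no history
    for (t in 2:Tn) {
      lo <- max(1L, t - W)
      n <- t - lo
      m <- (cs[t - 1L, ] - if (lo > 1L) cs[lo - 1L, ] else 0) / n
      s[t] <- sqrt(sum((y[t, ] - m)^2))
    }
    s
  })
  vals <- as.matrix(vals)
  structure(list(values = vals, warmup = seq_len(Tn) <= W,
                 frame_step = stream$frame_step, scene_id = stream$scene_id),
            class = "surprisal_matrix")
}

#' Wrap externally produced layer outputs as an embedding stream
#'
#' The adapter contract for any embedding provider: a list of per-layer
#' `T x K_l` matrices sharing the frame count and a frame step. Ragged frame
#' counts are rejected.
#'
#' @param layers List of numeric matrices, one per layer.
#' @param frame_step Seconds per frame.
#' @param scene_id Identifier.
#' @param expected_frame_step Optional check against the pipeline grid;
#'   mismatch is an error.
#' @return An `embedding_stream`.
#' @export
as_embedding_stream <- function(layers, frame_step, scene_id = "scene",
                                expected_frame_step = NULL) {
  layers <- lapply(layers, as.matrix)
  Tn <- unique(vapply(layers, nrow, integer(1)))
  if (length(Tn) != 1L) {
    stop("provider returned ragged frame counts across layers: ",
         paste(Tn, collapse = ", "))
  }
  if (any(vapply(layers, ncol, integer(1)) < 1L)) stop("layer dimension must be >= 1")
  if (!is.null(expected_frame_step) &&
      abs(frame_step - expected_frame_step) > 1e-9) {
    stop(sprintf("provider frame step %.4f s does not match configured %.4f s",
                 frame_step, expected_frame_step))
  }
  structure(list(layers = layers, frame_step = frame_step, scene_id = scene_id,
                 truth = NULL),
            class = "embedding_stream")
}

#' Construct a class-posterior table
#'
#' @param posteriors T x n_leaf matrix of per-frame class posteriors in
#'   \[0, 1\]; column names are leaf class ids.
#' @param ontology Two-column data.frame (`leaf`, `root`) mapping every leaf
#'   to one of the root classes (canonically Human, Things, Music, Animals,
#'   Background).
#' @param frame_step Seconds per frame.
#' @return A `posterior_table`.
#' @export
posterior_table <- function(posteriors, ontology, frame_step = 0.064) {
  posteriors <- as.matrix(posteriors)
  if (is.null(colnames(posteriors))) stop("posterior columns must be named leaf ids")
  if (any(posteriors < -1e-9 | posteriors > 1 + 1e-9)) {
    stop("posteriors must lie in [0, 1]")
  }
  ontology <- as.data.frame(ontology)
  if (!all(c("leaf", "root") %in% names(ontology))) {
    stop("`ontology` needs columns leaf, root")
  }
  miss <- setdiff(colnames(posteriors), ontology$leaf)
  if (length(miss)) stop("leaves missing from ontology: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ontology$leaf)) stop("every leaf must map to exactly one root")
  structure(list(values = posteriors, ontology = ontology,
                 frame_step = frame_step),
            class = "posterior_table")
}

#' Dominant root class of a segment by belief propagation
#'
#' Leaf posteriors are averaged over the segment; the 10 leaves with the
#' highest average posterior are the candidates (ties broken by
#' lexicographic leaf id); candidate posteriors are summed into their root
#' classes and the root with the maximum propagated belief wins (root ties
#' again lexicographic, flagged).
#'
#' @param post A [posterior_table()].
#' @param segment `c(start, end)` in seconds, end-exclusive.
#' @param n_candidates Number of candidate leaves (default 10).
#' @return List with `root`, `beliefs` (named vector), `candidates`,
#'   `tie` flag.
#' @export
dominant_class <- function(post, segment, n_candidates = 10L) {
  tt <- (seq_len(nrow(post$values)) - 1L) * post$frame_step
  sel <- tt >= segment[1L] - 1e-9 & tt < segment[2L] - 1e-9
  if (!any(sel)) stop("segment lies outside the stream")
  avg <- colMeans(post$values[sel, , drop = FALSE])
  ord <- order(-avg, names(avg))            # descending, lexicographic ties
  cand <- names(avg)[ord][seq_len(min(n_candidates, length(avg)))]
  roots <- post$ontology$root[match(cand, post$ontology$leaf)]
  beliefs <- tapply(avg[cand], roots, sum)
  beliefs <- beliefs[order(names(beliefs))]
  top <- max(beliefs)
  winners <- names(beliefs)[beliefs == top]
  list(root = sort(winners)[1L], beliefs = beliefs, candidates = cand,
       tie = length(winners) > 1L || top == 0)
}

#' Class-posterior change-detection signal
#'
#' The tagging baseline for onset detection: per-class posteriors are
#' binarised at `threshold`, median-filtered with an odd window of about
#' `median_win` seconds, and the absolute first differences are summed
#' across classes per frame.
#'
#' @param post A [posterior_table()].
#' @param threshold Binarisation threshold (default 0.5).
#' @param median_win Median filter width in seconds (default 1).
#' @return Numeric detection signal of length T (first frame 0).
#' @export
posterior_change_signal <- function(post, threshold = 0.5, median_win = 1.0) {
  b <- (post$values >= threshold) * 1
  w <- odd_window(median_win, post$frame_step)
  f <- apply(b, 2L, function(col) stats::runmed(col, k = w, endrule = "median"))
  f <- as.matrix(f)
  d <- abs(apply(f, 2L, function(col) c(0, diff(col))))
  rowSums(as.matrix(d))
}

#' A default synthetic ontology mapping
#'
#' Utility for synthetic posterior tables: leaves `H1..`, `T1..`, `M1..`,
#' `A1..`, `B1..` map to Human, Things, Music, Animals, Background by their
#' prefix.
#'
#' @param leaves Character vector of leaf ids.
#' @return data.frame with `leaf`, `root`.
#' @export
synthetic_ontology <- function(leaves) {
  pre <- substr(leaves, 1L, 1L)
  root <- c(H = "Human", T = "Things", M = "Music", A = "Animals",
            B = "Background")[pre]
  if (anyNA(root)) stop("leaf ids must start with H, T, M, A, or B")
  data.frame(leaf = leaves, root = unname(root))
}
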