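# Synthetic deep-embedding streams with planted semantic change points,
# plus the linear ground-truth salience generator used for filter-recovery
# experiments.

#' Generate a synthetic embedding stream with planted change points
#'
#' Each layer is stationary Gaussian noise around a layer mean; at every
#' change point the mean shifts by a random direction of Euclidean norm
#' `step_norm`, emulating a semantic change in the scene.
#'
#' @param n_frames Number of frames `T`.
#' @param layers Number of layers `L`.
#' @param dims Per-layer flattened dimension (scalar or length-`L`).
#' @param change_points Change-point times in seconds (inside the stream).
#' @param step_norm Euclidean norm of the mean shift at each change point.
#' @param noise_sd Within-segment noise standard deviation per dimension.
#' @param frame_step Frame step in seconds (default 0.064).
#' @param seed Integer seed.
#' @param scene_id Identifier.
#' @return An `embedding_stream`: list with `layers` (list of `T x K_l`
#'   matrices), `frame_step`, `scene_id`, and `truth` (the planted change
#'   points and step norm).
#' @export
make_embedding_stream <- function(n_frames, layers = 4L, dims = 8L,
                                  change_points = numeric(0), step_norm = 1,
                                  noise_sd = 1, frame_step = 0.064,
                                  seed = 1L, scene_id = "scene") {
  if (any(dims <= 0)) stop("`dims` must be positive")
  dims <- rep_len(as.integer(dims), layers)
  cp_frames <- as.integer(round(change_points / frame_step)) + 1L
  if (length(cp_frames) && (any(cp_frames < 2L) || any(cp_frames > n_frames))) {
    stop("change points must lie inside the stream")
  }
  with_seed(seed, {
    mats <- lapply(seq_len(layers), function(l) {
      K <- dims[l]
      mu <- matrix(0, n_frames, K)
      base <- stats::rnorm(K)
      level <- matrix(base, n_frames, K, byrow = TRUE)
      for (cp in cp_frames) {
        dir <- stats::rnorm(K)
        dir <- dir / sqrt(sum(dir^2)) * step_norm
        level[cp:n_frames, ] <- sweep(level[cp:n_frames, , drop = FALSE], 2L, dir, "+")
      }
      level + matrix(stats::rnorm(n_frames * K, sd = noise_sd), n_frames, K)
    })
    structure(list(layers = mats, frame_step = frame_step, scene_id = scene_id,
                   truth = list(change_points = change_points,
                                step_norm = step_norm, noise_sd = noise_sd)),
              class = "embedding_stream")
  })
}

#' Generate linear ground-truth salience from a feature matrix
#'
#' The salience trace is the causal convolution of the features with a known
#' per-feature lag filter plus a bias and Gaussian noise, affinely rescaled
#' into \[0, 1\]. Because the rescaling is affine (never clipping), the
#' generating filter remains exactly recoverable by a linear model, which is
#' what makes this the oracle for ridge parameter-recovery experiments.
#'
#' @param features Numeric `T x F` feature matrix (or a `feature_matrix`).
#' @param filter Numeric `n_lags x F` matrix of generating weights; lag 1 is
#'   the instantaneous term, lag k uses `x[t - k + 1]`.
#' @param noise_sigma Gaussian noise standard deviation (in units of the
#'   noise-free trace).
#' @param bias Scalar bias added before rescaling.
#' @param seed Integer seed.
#' @param scene_id Identifier for the resulting map.
#' @return A `salience_map` (see [salience_map()]) with an attached
#'   `truth` attribute carrying the generating filter, bias, noise level and
#'   the affine rescaling coefficients.
#' @export
make_linear_ground_truth <- function(features, filter, noise_sigma = 0,
                                     bias = 0, seed = 1L, scene_id = "scene") {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  filter <- as.matrix(filter)
  if (ncol(filter) != ncol(x)) stop("filter and features disagree in feature count")
  n_lags <- nrow(filter)
  if (n_lags > nrow(x)) stop("filter lag span exceeds feature duration")
  Tn <- nrow(x)
  y <- rep(bias, Tn)
  for (k in seq_len(n_lags)) {
    xk <- rbind(matrix(0, k - 1L, ncol(x)), x[seq_len(Tn - k + 1L), , drop = FALSE])
    y <- y + xk %*% filter[k, ]
  }
  y <- as.numeric(y)
  y <- with_seed(seed, y + stats::rnorm(Tn, sd = noise_sigma))
  lo <- min(y); hi <- max(y)
  if (hi > lo) {
    scale <- 1 / (hi - lo); shift <- -lo * scale
  } else {
    scale <- 0; shift <- 0.5   # constant trace maps to 0.5
  }
  vals <- y * scale + shift
  map <- salience_map(scene_id = scene_id, values = vals, grid_step = 0.064,
                      direction = "fwd", n_participants = NA_integer_)
  attr(map, "truth") <- list(filter = filter, bias = bias,
                             noise_sigma = noise_sigma,
                             scale = scale, shift = shift)
  map
}
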