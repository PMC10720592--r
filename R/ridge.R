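# The context-windowed block-ridge salience model. The model predicts each
# point of the average behavioral salience as a linear mapping from lagged
# acoustic features and (optionally) lagged layer-wise semantic surprisals,
#
#   r_hat[t] = Wa' a[t] + Ws' s[t] + b ,
#
# estimated by minimising the squared error plus separate L2 penalties
# lambda_a ||Wa||^2 + lambda_s ||Ws||^2 on the two blocks; the bias is
# unpenalised. The closed-form solution uses a diagonal penalty matrix.

#' Fit the block-ridge salience model
#'
#' The central fitting function of the package. Scenes are supplied as
#' parallel lists of feature matrices, optional surprisal matrices, and
#' target salience maps; designs are built per scene with [build_design()]
#' and stacked.
#'
#' @param features List of `feature_matrix` objects (or a single one).
#' @param targets List of [salience_map()]s aligned with `features`.
#' @param surprisals Optional list of `surprisal_matrix` objects, or `NULL`
#'   for an acoustic-only model.
#' @param design A [context_design()].
#' @param lambda_a,lambda_s Ridge penalties for the acoustic and semantic
#'   blocks (>= 0).
#' @return Object of class `salience_ridge` with components `coefficients`
#'   (named vector; first element `(bias)`), `W_a`, `W_s`, `lambda_a`,
#'   `lambda_s`, `design`, `blocks`, `lags_a`, `lags_s`, `feature_names`,
#'   `fitted`, `residuals`, `r_train`.
#' @export
fit_salience <- function(features, targets, surprisals = NULL,
                         design = context_design(),
                         lambda_a = 1, lambda_s = 1) {
  if (inherits(features, "feature_matrix")) features <- list(features)
  if (inherits(targets, "salience_map")) targets <- list(targets)
  if (!is.null(surprisals) && inherits(surprisals, "surprisal_matrix")) {
    surprisals <- list(surprisals)
  }
  if (length(features) != length(targets)) stop("features/targets length mismatch")
  if (lambda_a < 0 || lambda_s < 0) stop("penalties must be >= 0")
  Xs <- list(); ys <- list(); blocks <- NULL; lags_a <- NULL; lags_s <- NULL
  for (i in seq_along(features)) {
    d <- build_design(features[[i]],
                      if (is.null(surprisals)) NULL else surprisals[[i]],
                      design)
    y <- targets[[i]]$values
    if (length(y) != nrow(features[[i]]$values)) {
      stop("target length does not match feature frames for scene ", i)
    }
    Xs[[i]] <- d$X
    ys[[i]] <- y[d$rows]
    blocks <- d$blocks; lags_a <- d$lags_a; lags_s <- d$lags_s
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  fit <- ridge_solve(X, y, blocks, lambda_a, lambda_s)
  co <- fit$coef
  pred <- as.numeric(cbind(1, X) %*% co)
  structure(list(coefficients = co,
                 W_a = co[1L + blocks$acoustic],
                 W_s = if (!is.null(blocks$semantic)) co[1L + blocks$semantic],
                 lambda_a = lambda_a, lambda_s = lambda_s,
                 design = design, blocks = blocks,
                 lags_a = lags_a, lags_s = lags_s,
                 feature_names = features[[1L]]$names,
                 n_frames = length(y),
                 fitted = pred, residuals = y - pred,
                 r_train = suppressWarnings(stats::cor(pred, y)),
                 singular = fit$singular),
            class = "salience_ridge")
}

# Closed-form block-penalised ridge; pseudoinverse fallback (with warning)
# when the system is singular and unpenalised.
ridge_solve <- function(X, y, blocks, lambda_a, lambda_s) {
  Xi <- cbind(`(bias)` = 1, X)
  p <- ncol(Xi)
  pen <- numeric(p)
  pen[1L + blocks$acoustic] <- lambda_a
  if (!is.null(blocks$semantic)) pen[1L + blocks$semantic] <- lambda_s
  A <- crossprod(Xi) + diag(pen, p)
  b <- crossprod(Xi, y)
  co <- tryCatch(solve(A, b), error = function(e) NULL)
  singular <- is.null(co)
  if (singular) {
    warning("singular system; using the Moore-Penrose pseudoinverse")
    co <- MASS::ginv(A) %*% b
  }
  co <- as.numeric(co)
  names(co) <- colnames(Xi)
  list(coef = co, singular = singular)
}

#' @export
print.salience_ridge <- function(x, ...) {
  cat("<salience_ridge> block-ridge salience model\n")
  cat(sprintf("  acoustic block: %d weights (lags %d..%d), lambda_a = %g\n",
              length(x$W_a), min(x$lags_a), max(x$lags_a), x$lambda_a))
  if (!is.null(x$W_s)) {
    cat(sprintf("  semantic block: %d weights (lags %d..%d), lambda_s = %g\n",
                length(x$W_s), min(x$lags_s), max(x$lags_s), x$lambda_s))
  }
  cat(sprintf("  training frames: %d, training r = %.3f\n", x$n_frames, x$r_train))
  invisible(x)
}

#' @export
summary.salience_ridge <- function(object, ...) {
  trf <- trf_weights(object)
  structure(list(model = object,
                 trf_norms = sqrt(colSums(trf$acoustic^2)),
                 r_train = object$r_train), class = "summary.salience_ridge")
}

#' @export
print.summary.salience_ridge <- function(x, ...) {
  print(x$model)
  cat("  per-feature temporal-weight norms:\n")
  print(round(x$trf_norms, 4))
  invisible(x)
}

#' @export
coef.salience_ridge <- function(object, ...) object$coefficients

#' @export
residuals.salience_ridge <- function(object, ...) object$residuals

#' Predict salience for new scenes
#'
#' @param object A fitted `salience_ridge`.
#' @param features A `feature_matrix` or list of them.
#' @param surprisals Matching `surprisal_matrix` list if the model has a
#'   semantic block.
#' @param ... Unused.
#' @return For a single scene, a list with `pred` and `rows` (frame indices
#'   with full context); for a list of scenes, a list of those.
#' @export
predict.salience_ridge <- function(object, features, surprisals = NULL, ...) {
  single <- inherits(features, "feature_matrix")
  if (single) {
    features <- list(features)
    if (!is.null(surprisals)) surprisals <- list(surprisals)
  }
  if (!is.null(object$W_s) && is.null(surprisals)) {
    stop("model has a semantic block; `surprisals` are required")
  }
  out <- lapply(seq_along(features), function(i) {
    d <- build_design(features[[i]],
                      if (is.null(surprisals)) NULL else surprisals[[i]],
                      object$design)
    pred <- as.numeric(cbind(1, d$X) %*% object$coefficients)
    list(pred = pred, rows = d$rows)
  })
  if (single) out[[1L]] else out
}

#' Temporal response functions and feature autocorrelations
#'
#' Reshapes the fitted acoustic block weights to a lag x feature matrix
#' (the per-feature temporal response functions) and, when features are
#' supplied, computes each feature's autocorrelation function normalised to
#' 1 at lag 0 — the two sides of the weight-vs-dynamics comparison.
#'
#' @param model A fitted `salience_ridge` with a lagged design.
#' @param features Optional `feature_matrix` (or list) for the
#'   autocorrelation side.
#' @param max_lag_s Autocorrelation support in seconds.
#' @return List with `trf` (lag x feature), `lags_s` (lag times, s), and
#'   `autocorrelation` (lag x feature, if features given).
#' @export
trf_and_autocorrelation <- function(model, features = NULL, max_lag_s = 4) {
  if (length(model$lags_a) < 2L) stop("model has no lagged design")
  trf <- trf_weights(model)
  out <- list(trf = trf$acoustic, lags_s = model$lags_a * model$design$frame_step)
  if (!is.null(features)) {
    if (inherits(features, "feature_matrix")) features <- list(features)
    nl <- as.integer(round(max_lag_s / model$design$frame_step))
    acfs <- lapply(features, function(f) {
      apply(f$values, 2L, function(col) {
        a <- stats::acf(col, lag.max = nl, plot = FALSE)$acf[, 1, 1]
        a / a[1L]
      })
    })
    out$autocorrelation <- Reduce(`+`, acfs) / length(acfs)
    out$acf_lags_s <- (0:nl) * model$design$frame_step
  }
  out
}

# Acoustic (and semantic) weights reshaped to lag x feature matrices.
trf_weights <- function(model) {
  nf <- length(model$feature_names)
  wa <- matrix(model$W_a, nrow = length(model$lags_a), ncol = nf, byrow = TRUE)
  rownames(wa) <- paste0("lag", model$lags_a)
  colnames(wa) <- model$feature_names
  ws <- NULL
  if (!is.null(model$W_s)) {
    nl <- length(model$lags_s)
    ws <- matrix(model$W_s, nrow = nl, byrow = TRUE)
    rownames(ws) <- paste0("lag", model$lags_s)
  }
  list(acoustic = wa, semantic = ws)
}

#' @export
plot.salience_ridge <- function(x, features = NULL, ...) {
  trf <- trf_weights(x)$acoustic
  lag_s <- x$lags_a * x$design$frame_step
  norms <- sqrt(colSums(trf^2))
  top <- order(-norms)[seq_len(min(3L, ncol(trf)))]
  graphics::matplot(lag_s, trf[, top, drop = FALSE], type = "l", lty = 1,
                    xlab = "lag (s)", ylab = "weight",
                    main = "Temporal response functions (top features)", ...)
  graphics::legend("topright", legend = colnames(trf)[top],
                   col = seq_along(top), lty = 1, bty = "n")
  invisible(x)
}
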