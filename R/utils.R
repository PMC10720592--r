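# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls never
#' disturb the caller's RNG stream. All randomness in the package is routed
#' through this helper.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Column-wise z-scoring with a defined constant-column rule
#'
#' Columns with zero variance are mapped to all zeros (with a warning) rather
#' than dividing by zero; this keeps downstream regression designs finite for
#' degenerate inputs such as silence.
#'
#' @param x Numeric matrix.
#' @param warn Warn on constant columns.
#' @return Matrix of the same shape with each column standardised.
#' @keywords internal
zscore_cols <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad) && warn) {
    warning(sprintf("%d constant column(s) z-scored to zeros", sum(bad)))
  }
  sdv[bad] <- 1
  out <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
  out[, bad] <- 0
  out
}

#' Centered moving-average (box) smoothing with edge replication
#'
#' @param x Numeric vector.
#' @param width Window length in samples (coerced to an odd integer so the
#'   window is centered).
#' @param passes Number of repeated applications.
#' @return Smoothed vector of the same length.
#' @keywords internal
box_smooth <- function(x, width, passes = 1L) {
  n <- length(x)
  w <- as.integer(round(width))
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L || n == 0L) return(x)
  half <- (w - 1L) %/% 2L
  for (p in seq_len(passes)) {
    xp <- c(rep(x[1L], half), x, rep(x[n], half))
    cs <- cumsum(c(0, xp))
    x <- (cs[(w + 1L):(n + w)] - cs[1L:n]) / w
  }
  x
}

# Odd window length in samples for a duration in seconds on a given grid.
odd_window <- function(duration_s, step_s) {
  w <- as.integer(round(duration_s / step_s))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 1L)
}

# Zero-order-hold resampling of a step-wise trace onto a uniform grid.
# `t_in` are sample times of `x`; output has values x[last t_in <= t_out].
zoh_resample <- function(x, t_in, t_out) {
  idx <- findInterval(t_out, t_in)
  idx[idx < 1L] <- 1L
  x[idx]
}

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)))
  }
  invisible(x)
}
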