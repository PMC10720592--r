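# Temporal-context designs, the block-ridge model and its methods,
# segment evaluation, cross-validation, variants, ablation, and TRFs.

map_from <- function(values, scene_id = "s") {
  salience_map(scene_id, (values - min(values)) / (max(values) - min(values)))
}

test_that("designs reproduce lagged rows exactly", {
  x <- matrix(1:20, 10, 2)
  fm <- feature_matrix(x, frame_step = 0.064)
  des0 <- context_design(acoustic_smooth = 0, acoustic_past = 0,
                         acoustic_future = 0)
  d0 <- build_design(fm, design = des0)
  expect_equal(unname(d0$X), unname(x))
  des1 <- context_design(acoustic_smooth = 0, acoustic_past = 0.064,
                         acoustic_future = 0)
  d1 <- build_design(fm, design = des1)
  expect_equal(d1$rows, 2:10)
  expect_equal(unname(d1$X[3, ]), c(x[4, ], x[3, ]))   # [x_t, x_{t-1}]
  expect_error(build_design(fm, design = context_design(acoustic_past = 10)),
               "longer than the scene")
})

test_that("flattened designs equal the convolution formulation", {
  set.seed(1)
  fm <- smooth_features(120, n_feat = 3, seed = 2)
  filt <- matrix(rnorm(12), 4, 3)   # lags 0..3
  des <- context_design(acoustic_smooth = 0, acoustic_past = 3 * 0.064,
                        acoustic_future = 0)
  d <- build_design(fm, design = des)
  w_flat <- as.numeric(t(filt))     # lag-major to match design columns
  pred_design <- as.numeric(d$X %*% w_flat)
  x <- fm$values
  pred_conv <- rep(0, 120)
  for (k in 1:4) {
    xk <- rbind(matrix(0, k - 1, 3), x[1:(120 - k + 1), , drop = FALSE])
    pred_conv <- pred_conv + as.numeric(xk %*% filt[k, ])
  }
  expect_equal(pred_design, pred_conv[d$rows], tolerance = 1e-10)
})

test_that("infinite penalty shrinks to the target mean", {
  set.seed(3)
  fm <- smooth_features(300, n_feat = 4, seed = 4)
  y <- map_from(rnorm(300))
  m <- fit_salience(fm, y, design = context_design(acoustic_past = 0.128,
                                                   acoustic_future = 0),
                    lambda_a = 1e12)
  expect_lt(max(abs(m$W_a)), 1e-6)
  expect_equal(mean(m$fitted), mean(y$values), tolerance = 0.02)
  expect_lt(diff(range(m$fitted)), 1e-4)
})

test_that("noise-free linear targets are recovered to high precision", {
  set.seed(5)
  fm <- smooth_features(600, n_feat = 4, seed = 6)
  filt <- matrix(rnorm(12), 3, 4)
  gt <- make_linear_ground_truth(fm, filt, noise_sigma = 0, bias = 0.3)
  truth <- attr(gt, "truth")
  des <- context_design(acoustic_smooth = 0, acoustic_past = 2 * 0.064,
                        acoustic_future = 0)
  m <- fit_salience(fm, gt, design = des, lambda_a = 1e-8)
  w <- audsal:::trf_weights(m)$acoustic   # lags 0..2 x features
  expect_equal(unname(as.matrix(w)), unname(truth$filter * truth$scale),
               tolerance = 1e-6)
  expect_equal(m$r_train, 1, tolerance = 1e-9)
})

test_that("closed form matches a gradient-descent oracle", {
  set.seed(7)
  n <- 150; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  lam <- 2.5
  co <- audsal:::ridge_solve(X, y, list(acoustic = 1:p), lam, 0)$coef
  # oracle: plain gradient descent on the penalised least squares objective
  beta <- rep(0, p + 1)
  Xi <- cbind(1, X)
  pen <- c(0, rep(lam, p))
  L <- 2 * (max(eigen(crossprod(Xi), only.values = TRUE)$values) + lam)
  for (i in 1:200000) {
    g <- 2 * (as.numeric(crossprod(Xi, Xi %*% beta - y)) + pen * beta)
    beta <- beta - g / L
    if (sqrt(sum(g^2)) < 1e-10) break
  }
  expect_equal(unname(co), beta, tolerance = 1e-6)
})

test_that("unpenalised singular systems fall back to the pseudoinverse", {
  X <- cbind(1:10, (1:10) * 2)      # collinear
  expect_warning(
    audsal:::ridge_solve(X, rnorm(10), list(acoustic = 1:2), 0, 0),
    "pseudoinverse")
})

test_that("a semantic-only target leaves the acoustic block idle under heavy penalty", {
  set.seed(8)
  fm <- smooth_features(500, n_feat = 3, seed = 9)
  surr_raw <- smooth_features(500, n_feat = 2, seed = 10)
  surr <- structure(list(values = abs(surr_raw$values), frame_step = 0.064,
                         warmup = rep(FALSE, 500), scene_id = "s"),
                    class = "surprisal_matrix")
  y <- map_from(2 * surr$values[, 1] - surr$values[, 2])
  des <- context_design(acoustic_smooth = 0, semantic_smooth = 0,
                        acoustic_past = 0.128, acoustic_future = 0,
                        semantic_past = 0.128, semantic_future = 0)
  m1 <- fit_salience(fm, y, surr, design = des, lambda_a = 1e-4, lambda_s = 1e-4)
  m2 <- fit_salience(fm, y, surr, design = des, lambda_a = 1e6, lambda_s = 1e-4)
  expect_lt(max(abs(m2$W_a)), 1e-4)
  expect_lt(abs(m1$r_train - m2$r_train), 0.01)
})

test_that("segment correlations and categories follow the overlap rules", {
  set.seed(11)
  fm <- smooth_features(500, n_feat = 3, seed = 12)
  filt <- matrix(rnorm(3), 1, 3)
  gt <- make_linear_ground_truth(fm, filt, noise_sigma = 0)
  des <- context_design(acoustic_smooth = 0, acoustic_past = 0,
                        acoustic_future = 0)
  m <- fit_salience(fm, gt, design = des, lambda_a = 1e-8)
  seg <- evaluate_segments(m, fm, gt)
  expect_true(all(abs(seg$r - 1) < 1e-8))           # perfect model
  # constant-prediction segments are excluded and counted
  m0 <- m; m0$coefficients[] <- 0
  seg0 <- evaluate_segments(m0, fm, gt)
  expect_equal(nrow(seg0), 0)
  expect_gt(attr(seg0, "n_excluded"), 0)
  # hand-checkable tie-break: 3 s matched vs 2 s mismatched overlap
  ev <- ev_df(c(10, 14), c(13, 16))
  ev$label <- c("match", "mismatch")
  expect_equal(audsal:::segment_category(8, 16, ev), "match")
  expect_equal(audsal:::segment_category(30, 38, ev), "no-event")
  # brute-force oracle over random layouts
  for (rep in 1:100) {
    nev <- sample(0:5, 1)
    ev <- ev_df(sort(runif(nev, 0, 40)), numeric(nev))
    if (nev) { ev$offset <- ev$onset + runif(nev, 0.5, 5)
               ev$label <- sample(c("match", "mismatch"), nev, replace = TRUE) }
    s0 <- runif(1, 0, 30)
    got <- audsal:::segment_category(s0, s0 + 8, ev)
    ref <- {
      if (!nev) "no-event" else {
        ovl <- vapply(seq_len(nev), function(i) {
          max(0, min(s0 + 8, ev$offset[i]) - max(s0, ev$onset[i]))
        }, numeric(1))
        tot <- tapply(ovl, ev$label, sum)
        if (all(tot == 0)) "no-event" else names(tot)[which.max(tot)]
      }
    }
    expect_identical(got, ref)
  }
})

test_that("held-out correlations are invariant to affine target rescaling", {
  set.seed(13)
  fm <- smooth_features(400, n_feat = 3, seed = 14)
  y <- map_from(as.numeric(fm$values %*% c(1, -1, 0.5)) + rnorm(400, sd = 0.3))
  m <- fit_salience(fm, y, lambda_a = 1)
  seg1 <- evaluate_segments(m, fm, y)
  y2 <- y; y2$values <- 0.2 + 0.5 * y$values
  seg2 <- evaluate_segments(m, fm, y2)
  expect_equal(seg1$r, seg2$r, tolerance = 1e-10)
})

test_that("cross-validation is deterministic and honours one-point grids", {
  set.seed(15)
  feats <- lapply(1:4, function(i) smooth_features(250, n_feat = 3, seed = 20 + i))
  maps <- lapply(feats, function(f) {
    map_from(as.numeric(f$values %*% c(1, 0.5, -1)) + rnorm(250, sd = 0.2))
  })
  grid <- data.frame(lambda_a = 1, acoustic_past = 0.5, acoustic_future = 0)
  cv1 <- cross_validate(feats, maps, grid = grid, n_folds = 2, seed = 3)
  cv2 <- cross_validate(feats, maps, grid = grid, n_folds = 2, seed = 3)
  expect_equal(cv1$best, grid)
  expect_identical(cv1$fold_of, cv2$fold_of)
  expect_identical(cv1$scores, cv2$scores)
  expect_error(cross_validate(feats, maps, grid = grid[0, , drop = FALSE]),
               "empty")
})

test_that("variant caps coincide when contexts are equal and semantics are guarded", {
  set.seed(16)
  feats <- lapply(1:2, function(i) smooth_features(300, n_feat = 3, seed = 30 + i))
  maps <- lapply(feats, function(f) map_from(f$values[, 1] + rnorm(300, sd = 0.1)))
  mv <- model_variants(feats, maps, short_ctx = 1, long_ctx = 1, future_ctx = 0)
  expect_equal(mv$A_only$coefficients, mv$A_C$coefficients, tolerance = 1e-8)
  expect_error(model_variants(feats, maps, variants = c("A_S")), "require")
})

test_that("temporal response functions mirror feature dynamics", {
  set.seed(17)
  # white-noise feature: autocorrelation is a delta at lag 0
  wn <- feature_matrix(matrix(rnorm(2000), 2000, 1), frame_step = 0.064)
  y <- map_from(wn$values[, 1])
  m <- fit_salience(wn, y, design = context_design(acoustic_smooth = 0,
                                                   acoustic_past = 0.5,
                                                   acoustic_future = 0),
                    lambda_a = 0.01)
  ta <- trf_and_autocorrelation(m, wn, max_lag_s = 0.5)
  expect_equal(unname(ta$autocorrelation[1, 1]), 1)
  expect_lt(max(abs(ta$autocorrelation[-1, 1])), 0.1)
  # AR(1) feature: autocorrelation ~ rho^k
  rho <- 0.8
  ar <- feature_matrix(matrix(as.numeric(stats::filter(rnorm(4000), rho,
                                                       "recursive"))),
                       frame_step = 0.064)
  m2 <- fit_salience(ar, map_from(ar$values[, 1]),
                     design = context_design(acoustic_smooth = 0,
                                             acoustic_past = 0.5,
                                             acoustic_future = 0),
                     lambda_a = 0.01)
  ta2 <- trf_and_autocorrelation(m2, ar, max_lag_s = 0.32)
  expect_equal(as.numeric(ta2$autocorrelation[, 1]), rho^(0:5), tolerance = 0.1)
  # reshape round trip
  w <- audsal:::trf_weights(m2)$acoustic
  expect_equal(as.numeric(t(w)), unname(m2$W_a))
  m_nolag <- fit_salience(wn, y, design = context_design(acoustic_smooth = 0,
                                                         acoustic_past = 0,
                                                         acoustic_future = 0))
  expect_error(trf_and_autocorrelation(m_nolag), "no lagged design")
})

test_that("layer ablation jumps when the informative layer enters", {
  set.seed(18)
  # layers are independent streams with disjoint change points, so only
  # layer 2's surprisal is informative about the target
  mk_scene <- function(seed) {
    fm <- smooth_features(400, n_feat = 2, seed = seed)
    streams <- lapply(1:3, function(l) {
      cps <- if (l == 2) c(6.4, 12.8, 19.2) else numeric(0)
      make_embedding_stream(400, layers = 1, dims = 4, change_points = cps,
                            step_norm = 4, noise_sd = 0.5,
                            seed = seed * 10 + l)
    })
    su_cols <- sapply(streams, function(s) layer_surprisal(s)$values[, 1])
    su <- structure(list(values = su_cols, warmup = rep(FALSE, 400),
                         frame_step = 0.064, scene_id = "s"),
                    class = "surprisal_matrix")
    target <- map_from(0.3 * fm$values[, 1] + 2 * su$values[, 2] +
                         rnorm(400, sd = 0.1))
    list(fm = fm, su = su, target = target)
  }
  train <- lapply(1:3, mk_scene); test <- lapply(4:5, mk_scene)
  res <- layer_ablation(lapply(train, `[[`, "fm"), lapply(train, `[[`, "target"),
                        lapply(train, `[[`, "su"),
                        lapply(test, `[[`, "fm"), lapply(test, `[[`, "target"),
                        lapply(test, `[[`, "su"),
                        lambda_a = 1, lambda_s = 1, n_random = 5, seed = 2)
  expect_equal(res$cutoff, 0:3)
  gain2 <- res$r[res$cutoff == 2] - res$r[res$cutoff == 1]
  gain1 <- res$r[res$cutoff == 1] - res$r[res$cutoff == 0]
  expect_gt(gain2, 0.1)
  expect_gt(gain2, gain1 + 0.05)
  # random baseline stays flat within its own sampling noise
  rng <- range(res$r_random_mean[res$cutoff > 0])
  expect_lt(diff(rng), 6 * max(res$r_random_se) + 0.02)
})

test_that("class-wise tests localise a planted semantic benefit", {
  set.seed(19)
  n <- 40
  seg_a <- data.frame(scene = "s", start = seq_len(n) * 8, end = seq_len(n) * 8 + 8,
                      r = runif(n, 0.3, 0.5),
                      category = "match",
                      root = rep(c("Human", "Things"), each = n / 2))
  seg_b <- seg_a
  hum <- seg_b$root == "Human"
  seg_b$r[hum] <- seg_b$r[hum] + 0.2              # benefit only for Human
  seg_b$r[!hum] <- seg_b$r[!hum] + rnorm(sum(!hum), 0, 0.01)
  res <- classwise_performance(seg_a, seg_b)
  expect_equal(sum(res$n), n)
  expect_lt(res$p_value[res$root == "Human"], 1e-4)
  expect_gt(res$p_value[res$root == "Things"], 0.05)
})

test_that("the generating filter is recovered at realistic noise levels", {
  set.seed(20)
  n_scenes <- 6
  feats <- lapply(1:n_scenes, function(i) smooth_features(900, n_feat = 5,
                                                          seed = 40 + i))
  filt <- matrix(rnorm(5 * 8, sd = 0.4) * rep(exp(-(0:7) / 3), 5), 8, 5)
  gts <- lapply(seq_along(feats), function(i) {
    x <- feats[[i]]$values
    clean <- rep(0, 900)
    for (k in 1:8) {
      xk <- rbind(matrix(0, k - 1, 5), x[1:(900 - k + 1), , drop = FALSE])
      clean <- clean + as.numeric(xk %*% filt[k, ])
    }
    sigma <- sd(clean) / sqrt(10)                  # SNR 10
    make_linear_ground_truth(feats[[i]], filt, noise_sigma = sigma,
                             seed = 50 + i, scene_id = paste0("s", i))
  })
  des <- context_design(acoustic_smooth = 0, acoustic_past = 7 * 0.064,
                        acoustic_future = 0)
  m <- fit_salience(feats, gts, design = des, lambda_a = 1)
  w <- as.numeric(audsal:::trf_weights(m)$acoustic)
  g <- as.numeric(filt)
  cosine <- sum(w * g) / sqrt(sum(w^2) * sum(g^2))
  expect_gt(cosine, 0.9)
})
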