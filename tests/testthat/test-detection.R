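# Detection datasets, the shared-temporal-weight SGD detector, ROC/AUROC,
# the interobserver ceiling, and the tagging-posterior baseline.

bumpy_features <- function(n_frames, onsets, seed, bump = 4, n_feat = 6) {
  v <- audsal:::synthetic_feature_stream(n_frames, onsets, 0.064, seed,
                                         n_features = n_feat, bump = bump)
  feature_matrix(v, frame_step = 0.064)
}

test_that("detection labels follow the half-open segment convention", {
  fm <- bumpy_features(500, numeric(0), seed = 1)
  ds0 <- make_detection_dataset(fm, numeric(0))
  expect_true(all(ds0$y == 0))
  # an onset exactly on a boundary belongs to the segment it starts
  ds <- make_detection_dataset(fm, events = ds0$starts[3])
  expect_equal(which(ds$y == 1), 3)
  # sparse planted onsets -> one positive per onset
  on <- c(3.2, 9.6, 16.0, 22.4)
  ds2 <- make_detection_dataset(fm, on)
  expect_equal(sum(ds2$y), length(on))
  expect_error(make_detection_dataset(bumpy_features(20, numeric(0), 2),
                                      numeric(0), seg_s = 10), "shorter")
})

test_that("the detector separates separable data and is seed reproducible", {
  set.seed(2)
  on <- seq(3.2, 60, by = 6.4)
  fm <- bumpy_features(1000, on, seed = 3, bump = 6)
  ds <- make_detection_dataset(fm, on)
  expect_error(fit_detector(structure(list(x = ds$x[ds$y == 0, , ],
                                           y = ds$y[ds$y == 0],
                                           variant = "A"),
                                      class = "detection_dataset")),
               "both classes")
  d1 <- fit_detector(ds, epochs = 200, batch_size = 16, seed = 4)
  d2 <- fit_detector(ds, epochs = 200, batch_size = 16, seed = 4)
  expect_identical(d1$v, d2$v)
  expect_identical(d1$u, d2$u)
  r <- roc(d1, dataset = ds)
  expect_gt(r$auroc, 0.95)
  expect_lte(min(diff(d1$loss[c(1, d1$best_epoch)])), 0)  # loss decreased
})

test_that("label shuffling drives the detector to chance", {
  set.seed(5)
  on <- seq(3.2, 60, by = 6.4)
  fm <- bumpy_features(1000, on, seed = 6, bump = 6)
  ds <- make_detection_dataset(fm, on)
  # shuffled labels, scored on held-out segments: chance performance
  n <- length(ds$y)
  aurocs <- vapply(1:10, function(s) {
    y_shuf <- sample(ds$y)
    tr_idx <- sample(n, n %/% 2)
    te_idx <- setdiff(seq_len(n), tr_idx)
    sub <- function(idx) structure(list(x = ds$x[idx, , , drop = FALSE],
                                        y = y_shuf[idx],
                                        starts = ds$starts[idx],
                                        seg_s = ds$seg_s, variant = "A"),
                                   class = "detection_dataset")
    det <- fit_detector(sub(tr_idx), epochs = 40, batch_size = 16, seed = s)
    roc(predict(det, sub(te_idx)), y_shuf[te_idx])$auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})

test_that("ROC is monotone, anchored, and equals the rank-based oracle", {
  set.seed(7)
  y <- rep(c(0, 1), each = 40)
  s <- rnorm(80) + y
  r <- roc(s, y)
  expect_true(all(diff(r$hit) >= 0))
  expect_true(all(diff(r$fa) >= 0))
  expect_equal(c(r$hit[1], r$fa[1]), c(0, 0))
  expect_equal(c(r$hit[length(r$hit)], r$fa[length(r$fa)]), c(1, 1))
  # Mann-Whitney normalisation
  u <- wilcox.test(s[y == 1], s[y == 0])$statistic
  expect_equal(r$auroc, unname(u) / (40 * 40), tolerance = 1e-10)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(r$auroc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
  }
  expect_equal(roc(y, y)$auroc, 1)
  expect_equal(roc(rep(0.5, 80), y)$auroc, 0.5)
  expect_error(roc(s, rep(1, 80)), "at least one")
})

test_that("interobserver counts form a ceiling detection signal", {
  on <- c(10, 25, 40)
  truth <- list(scene_id = "s", planted_onsets = on)
  rs <- response_spec(n_participants = 30, consensus = 1, rt_median = 1.0,
                      rt_spread = 0, lapse_rate = 0, hold = 3)
  tr <- make_response_set(truth, rs, 55, seed = 8)
  fm <- bumpy_features(800, on, seed = 9)
  ds <- make_detection_dataset(fm, on)
  counts <- interobserver_signal(tr, ds$starts, ds$seg_s, rt_shift = 1)
  expect_true(all(counts >= 0 & counts <= 30))
  expect_true(all(counts == round(counts)))
  expect_equal(roc(counts, ds$y)$auroc, 1)
  # a lapse-only cohort carries no onset information
  rs_l <- response_spec(n_participants = 30, consensus = 0, rt_median = 1,
                        rt_spread = 0, lapse_rate = 0.1)
  tr_l <- make_response_set(truth, rs_l, 55, seed = 10)
  counts_l <- interobserver_signal(tr_l, ds$starts, ds$seg_s)
  expect_lt(abs(roc(counts_l + runif(length(counts_l)) * 1e-6, ds$y)$auroc - 0.5),
            0.2)
})

test_that("posterior-change baseline finds aligned class switches only", {
  on <- c(6.4, 19.2, 32.0)
  fm <- bumpy_features(700, on, seed = 11)
  ds <- make_detection_dataset(fm, on)
  leaves <- c("H1", "T1", "M1")
  nT <- 700
  tt <- (seq_len(nT) - 1) * 0.064
  aligned <- matrix(0.05, nT, 3, dimnames = list(NULL, leaves))
  edges <- c(0, on, Inf)
  for (s in 1:4) aligned[tt >= edges[s] & tt < edges[s + 1], ((s - 1) %% 3) + 1] <- 0.9
  p_al <- posterior_table(aligned, synthetic_ontology(leaves))
  expect_gt(baseline_posterior_change(p_al, ds)$auroc, 0.9)
  # switches independent of the onsets: chance
  misaligned <- matrix(0.05, nT, 3, dimnames = list(NULL, leaves))
  edges2 <- c(0, on + 3.3, Inf)
  for (s in 1:4) misaligned[tt >= edges2[s] & tt < edges2[s + 1], ((s - 1) %% 3) + 1] <- 0.9
  p_mis <- posterior_table(misaligned, synthetic_ontology(leaves))
  expect_lt(baseline_posterior_change(p_mis, ds)$auroc, 0.7)
  # constant posteriors: degenerate single-threshold ROC at chance
  p_const <- posterior_table(matrix(0.8, nT, 3, dimnames = list(NULL, leaves)),
                             synthetic_ontology(leaves))
  expect_equal(baseline_posterior_change(p_const, ds)$auroc, 0.5)
})

test_that("the A-S variant beats A-only when onsets are embedding driven", {
  set.seed(12)
  wins <- vapply(1:12, function(s) {
    on <- sort(runif(5, 5, 55))
    on <- on[c(TRUE, diff(on) > 5)]
    # acoustics carry no onset information; embeddings step at onsets
    fm <- bumpy_features(1000, numeric(0), seed = 100 + s, bump = 0)
    st <- make_embedding_stream(1000, layers = 2, dims = 6,
                                change_points = on, step_norm = 8,
                                noise_sd = 0.3, seed = 200 + s)
    su <- layer_surprisal(st)
    ds_a <- make_detection_dataset(fm, on)
    ds_as <- make_detection_dataset(fm, on, surprisal = su)
    auc_a <- roc(fit_detector(ds_a, epochs = 60, seed = s),
                 dataset = ds_a)$auroc
    auc_as <- roc(fit_detector(ds_as, epochs = 60, seed = s),
                  dataset = ds_as)$auroc
    auc_as > auc_a
  }, logical(1))
  expect_lt(binom.test(sum(wins), length(wins), alternative = "greater")$p.value,
            0.05)
})

test_that("the interobserver ceiling dominates a fitted detector", {
  set.seed(13)
  on <- seq(8, 100, by = 11)
  truth <- list(scene_id = "s", planted_onsets = on)
  rs <- response_spec(n_participants = 80, consensus = 0.6, rt_median = 0.9,
                      rt_spread = 0.14, lapse_rate = 0.005)
  tr <- make_response_set(truth, rs, 110, seed = 14)
  m <- average_behavioral_salience(tr)
  ev <- extract_events(m)
  fm <- bumpy_features(length(m$values), ev$onset, seed = 15, bump = 2)
  ds <- make_detection_dataset(fm, ev)
  det <- fit_detector(ds, epochs = 80, seed = 16)
  auc_model <- roc(det, dataset = ds)$auroc
  counts <- interobserver_signal(tr, ds$starts, ds$seg_s)
  auc_ceiling <- roc(counts, ds$y)$auroc
  expect_gte(auc_ceiling, auc_model)
})
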