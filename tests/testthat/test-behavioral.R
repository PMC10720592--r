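# Quality control, salience-map construction, reaction times, and
# forward/backward agreement.

make_trial <- function(att, fs = 20, pid = "P001", sid = "s", dir = "fwd") {
  list(participant_id = pid, scene_id = sid, direction = dir,
       opposing_scene_id = NA_character_,
       t = (seq_along(att) - 1) / fs, attending = as.integer(att))
}

test_that("switching rate counts transitions per second", {
  n <- 20 * 120
  expect_equal(switching_rate(make_trial(rep(1, n))), 0)
  tr <- rep(0, n); tr[c(200, 500, 900, 1300, 1700, 1900, 2000, 2100, 2200, 2300)] <- 1
  # each isolated 1 gives two transitions: 10 placed ones -> 20 transitions
  expect_equal(switching_rate(make_trial(tr)), 20 / 120)
  alt <- rep_len(c(0, 1), n)
  expect_equal(switching_rate(make_trial(alt)), (n - 1) / 120, tolerance = 1e-6)
  expect_gt(switching_rate(make_trial(alt)), 19)
})

test_that("quality control excludes exactly the planted spammers", {
  set.seed(42)
  n <- 20 * 60
  trials <- list()
  for (p in 1:60) {          # normal participants: ~0.4 switches/s
    for (tr in 1:10) {
      att <- rep(0, n)
      k <- sample(n - 10, 12)
      for (x in k) att[x:(x + 4)] <- 1
      trials[[length(trials) + 1]] <- make_trial(att, pid = sprintf("N%02d", p),
                                                 sid = paste0("sc", tr))
    }
  }
  for (p in 1:5) {           # spammers alternate every sample in all trials
    for (tr in 1:10) {
      trials[[length(trials) + 1]] <- make_trial(rep_len(c(0, 1), n),
                                                 pid = sprintf("SPAM%d", p),
                                                 sid = paste0("sc", tr))
    }
  }
  qc <- quality_control(structure(trials, class = "trial_set"))
  expect_setequal(qc$excluded, sprintf("SPAM%d", 1:5))
})

test_that("all-equal switching rates exclude no one", {
  trials <- lapply(1:10, function(p) {
    att <- rep(0, 1200); att[600:1200] <- 1
    make_trial(att, pid = sprintf("P%02d", p))
  })
  qc <- quality_control(structure(trials, class = "trial_set"))
  expect_length(qc$excluded, 0)
})

test_that("exactly max_abnormal abnormal trials is retained (strictly more excludes)", {
  set.seed(7)
  n <- 1200
  trials <- list()
  for (p in 1:12) {
    for (tr in 1:10) {
      att <- rep(0, n)
      for (x in sample(n - 10, 12)) att[x:(x + 4)] <- 1
      trials[[length(trials) + 1]] <- make_trial(att, pid = sprintf("P%02d", p),
                                                 sid = paste0("sc", tr))
    }
  }
  spam <- function(pid, k) lapply(1:k, function(tr) {
    make_trial(rep_len(c(0, 1), n), pid = pid, sid = paste0("sp", tr))
  })
  trials <- c(trials, spam("EDGE", 5), spam("OVER", 6))
  qc <- quality_control(structure(trials, class = "trial_set"))
  expect_false("EDGE" %in% qc$excluded)
  expect_true("OVER" %in% qc$excluded)
})

test_that("a single step trace maps to a ramp centered near t0 - rt_shift", {
  n <- 20 * 60
  att <- rep(0, n); att[(20 * 30 + 1):n] <- 1   # step at t = 30
  m <- average_behavioral_salience(structure(list(make_trial(att)),
                                             class = "trial_set"))
  tt <- (seq_along(m$values) - 1) * m$grid_step
  expect_equal(max(m$values), 1)
  expect_true(all(m$values[tt > 32] == 1))
  # half-crossing at the shifted step location (29 s)
  cross <- tt[min(which(m$values >= 0.5))]
  expect_lt(abs(cross - 29), 0.15)
})

test_that("complementary traces average to one half in the interior", {
  n <- 20 * 40
  a <- rep_len(c(rep(0, 100), rep(1, 100)), n)
  m <- average_behavioral_salience(structure(
    list(make_trial(a), make_trial(1 - a, pid = "P002")), class = "trial_set"))
  interior <- m$values[100:(length(m$values) - 100)]
  expect_true(all(abs(interior - 0.5) < 1e-9))
})

test_that("impulse response equals the analytic triple-box kernel", {
  n <- 20 * 60
  att <- rep(0, n); att[20 * 30] <- 1
  m <- average_behavioral_salience(structure(list(make_trial(att)),
                                             class = "trial_set"))
  # oracle: convolve three discrete boxes of the same odd length
  w <- 23  # round(1.5 / 0.064) rounded up to odd
  box <- rep(1 / w, w)
  kern <- convolve(convolve(box, rev(box), type = "open"), rev(box), type = "open")
  got <- m$values[m$values > 0]
  # the single input sample survives on the 64 ms grid as one frame of
  # amplitude 1; compare shapes after peak alignment
  expect_equal(sum(got), sum(kern) / sum(box) * 1, tolerance = 1e-6)
  ip <- which.max(got); ik <- which.max(kern)
  span <- -min(ip, ik):(min(length(got) - ip, length(kern) - ik))
  expect_lt(max(abs(got[ip + span] - kern[ik + span])), 1e-8)
  # total support is 3 windows ~ 4.5 s
  expect_equal(length(got), length(kern), tolerance = 0.05)
})

test_that("smoothing conserves the interior mean and participant order", {
  set.seed(3)
  n <- 20 * 50
  trials <- lapply(1:8, function(p) {
    att <- rep(0, n)
    for (x in sample(n - 40, 6)) att[x:(x + 30)] <- 1
    make_trial(att, pid = sprintf("P%02d", p))
  })
  ts1 <- structure(trials, class = "trial_set")
  ts2 <- structure(rev(trials), class = "trial_set")
  m1 <- average_behavioral_salience(ts1)
  m2 <- average_behavioral_salience(ts2)
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
  # mean conservation vs the unsmoothed average, away from the edges
  raw <- rowMeans(vapply(trials, function(tr) {
    audsal:::zoh_resample(tr$attending, tr$t - 1, seq(0, 50 - 0.032, by = 0.064))
  }, numeric(length(m1$values))))
  inner <- 80:(length(raw) - 80)
  expect_lt(abs(mean(m1$values[inner]) - mean(raw[inner])), 1e-3)
})

test_that("triple box smoothing equals one pass with the composed kernel", {
  set.seed(5)
  x <- rnorm(600)
  w <- 23L
  three <- audsal:::box_smooth(x, w, passes = 3)
  box <- rep(1 / w, w)
  kern <- convolve(convolve(box, rev(box), type = "open"), rev(box), type = "open")
  half <- (length(kern) - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[600], half))
  one <- stats::filter(xp, kern, sides = 2)[(half + 1):(half + 600)]
  # interior agreement (edge replication differs slightly at the rims)
  expect_lt(max(abs(three[40:560] - one[40:560])), 1e-6)
})

test_that("reaction times recover the simulated offset from planted onsets", {
  truth <- list(scene_id = "s", planted_onsets = c(12, 30))
  rs <- response_spec(n_participants = 20, consensus = 1, rt_median = 0.9,
                      rt_spread = 0, lapse_rate = 0, hold = 4)
  tr <- make_response_set(truth, rs, 45, seed = 2)
  rts <- individual_reaction_times(tr, truth$planted_onsets)
  expect_true(all(rts$n_responsive == 2))
  # traces shifted by 1 s: switch lands at rt_median - rt_shift = -0.1
  expect_true(all(abs(rts$mean_rt - (0.9 - 1.0)) < 0.06))
})

test_that("non-responsive participants are flagged, exact-onset switch is zero", {
  flat <- make_trial(rep(0, 600))
  rts <- individual_reaction_times(structure(list(flat), class = "trial_set"), 10)
  expect_true(is.na(rts$mean_rt))
  expect_equal(rts$n_responsive, 0)
  att <- rep(0, 600); att[(20 * 11 + 1):600] <- 1   # raw switch at 11 s
  rts2 <- individual_reaction_times(structure(list(make_trial(att)),
                                              class = "trial_set"),
                                    events = 10, rt_shift = 1)
  expect_equal(rts2$mean_rt, 0, tolerance = 0.051)
})

test_that("agreement is 1 for a map against itself and -1 under inversion", {
  set.seed(8)
  v <- audsal:::box_smooth(runif(500), 15, 2)
  m <- salience_map("s", v)
  mr <- salience_map("s", rev(v), direction = "bwd")
  expect_equal(fwd_bwd_agreement(m, mr)$rho, 1)
  minv <- salience_map("s", 1 - rev(v), direction = "bwd")
  expect_equal(fwd_bwd_agreement(m, minv)$rho, -1)
  expect_error(fwd_bwd_agreement(m, salience_map("other", v)), "different scenes")
  expect_error(fwd_bwd_agreement(m, salience_map("s", v[1:400])), "more than one")
})

test_that("independent random maps correlate near zero on average", {
  set.seed(13)
  pairs <- replicate(100, {
    a <- audsal:::box_smooth(runif(400), 23, 3)
    b <- audsal:::box_smooth(runif(400), 23, 3)
    cor(a, rev(b), method = "spearman")
  })
  expect_lt(abs(mean(pairs)), 0.1)
})

test_that("noise floor is reproducible, near zero, and excludes degenerate pairs", {
  set.seed(21)
  fwd <- lapply(1:6, function(i) salience_map(paste0("s", i),
                                              audsal:::box_smooth(runif(400), 23, 3)))
  bwd <- lapply(1:6, function(i) salience_map(paste0("s", i),
                                              audsal:::box_smooth(runif(400), 23, 3),
                                              direction = "bwd"))
  nf1 <- noise_floor(fwd, bwd, n_perm = 30, seed = 4)
  nf2 <- noise_floor(fwd, bwd, n_perm = 30, seed = 4)
  expect_identical(nf1$rhos, nf2$rhos)
  expect_lt(abs(nf1$mean), 0.12)
  expect_error(noise_floor(fwd[1], bwd[1]), "at least 2")
  # constant maps are excluded, not propagated as NaN
  fwd2 <- fwd; fwd2[[1]]$values <- rep(0.5, 400)
  nfc <- noise_floor(fwd2, bwd, n_perm = 5, seed = 1)
  expect_gt(nfc$n_excluded, 0)
  expect_false(anyNA(nfc$rhos))
})

test_that("pipeline round trip recovers the configured consensus plateau", {
  truth <- list(scene_id = "s", planted_onsets = 20)
  cons <- 0.6; n <- 150
  rs <- response_spec(n_participants = n, consensus = cons, rt_median = 0.9,
                      rt_spread = 0.1, lapse_rate = 0, hold = 5)
  tr <- make_response_set(truth, rs, 45, seed = 6)
  m <- average_behavioral_salience(tr)
  tt <- (seq_along(m$values) - 1) * m$grid_step
  plateau <- max(m$values[tt > 19 & tt < 24])
  se <- sqrt(cons * (1 - cons) / n)
  expect_lt(abs(plateau - cons), 3 * se)
})
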