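test_that("simulated EEG trials are deterministic and validated", {
  cfg <- small_cfg()
  t1 <- simulate_eeg_trial(cfg, 2, 4, seed = 9)
  t2 <- simulate_eeg_trial(cfg, 2, 4, seed = 9)
  expect_identical(t1$data, t2$data)
  expect_equal(dim(t1$data), c(30, 2000))
  expect_identical(t1$channel_names, emofuse_montage())
  expect_error(simulate_eeg_trial(cfg, 0, 3), "between 1 and 5")
  expect_error(simulate_eeg_trial(cfg, 3, 6), "between 1 and 5")
  expect_error(sim_config(n_channels = 32), "fixed at 30")
  expect_error(sim_config(trial_duration_s = 8.123,
                          sampling_rate_hz = 250), "integer sample count")
})

test_that("zero valence asymmetry leaves no systematic hemispheric APS difference", {
  # With asymmetry 0 the construction is left-right symmetric, so expected
  # DAPS is 0 on every pair: per-entry t statistics over trials stay within
  # chance bounds (Bonferroni-style cap for 60 entries).
  cfg <- sim_config(n_trials_per_level = 1, trial_duration_s = 2,
                    valence_asymmetry_per_level = rep(0, 5), seed = 1)
  w <- hamming_window(500)
  dvals <- sapply(1:40, function(i) {
    tr <- simulate_eeg_trial(cfg, 3, 5, seed = 100 + i)
    daps(tr$data * rep(w, each = 30), tr$channel_names, 250)
  })
  tstat <- rowMeans(dvals) / (apply(dvals, 1, sd) / sqrt(ncol(dvals)))
  expect_lt(max(abs(tstat)), 5)
})

test_that("broadband energy increases strictly with the arousal level", {
  cfg <- sim_config(n_trials_per_level = 1, trial_duration_s = 2, seed = 3)
  broad <- list(name = "broad", low_hz = 1, high_hz = 45)
  mean_ae <- sapply(1:5, function(lev) {
    mean(sapply(1:50, function(i) {
      tr <- simulate_eeg_trial(cfg, lev, 3, seed = lev * 1000 + i)
      band_average_energy(tr$data[1, ], 250, broad)
    }))
  })
  expect_true(all(diff(mean_ae) > 0))
})

test_that("eye records have ordered, positive, in-trial events", {
  cfg <- small_cfg(dur = 55)
  for (i in 1:5) {
    rec <- simulate_eye_record(cfg, sample(1:5, 1), sample(1:5, 1),
                               seed = 500 + i)
    ev <- rec$events
    expect_true(all(diff(ev$onset_s) > 0))
    expect_true(all(ev$duration_s > 0))
    expect_true(all(ev$onset_s + ev$duration_s <= cfg$trial_duration_s + 1e-9))
    # Events do not overlap.
    expect_true(all(ev$onset_s[-1] >=
                      (ev$onset_s + ev$duration_s)[-nrow(ev)] - 1e-9))
  }
  r1 <- simulate_eye_record(cfg, 3, 3, seed = 7)
  r2 <- simulate_eye_record(cfg, 3, 3, seed = 7)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$pupil, r2$pupil)
})

test_that("pupil-luminance correlation vanishes without coupling", {
  cfg <- sim_config(n_trials_per_level = 1, trial_duration_s = 55,
                    illum_coupling = 0, seed = 2)
  r <- sapply(1:30, function(i) {
    rec <- simulate_eye_record(cfg, 3, 3, seed = 600 + i)
    cor(rec$pupil, rec$luminance)
  })
  expect_lt(abs(mean(r)), 0.1)
})

test_that("doubled blink rates separate levels by the blink-frequency feature", {
  cfg <- sim_config(n_trials_per_level = 1, trial_duration_s = 55, seed = 4)
  bf <- function(lev, i) {
    rec <- simulate_eye_record(cfg, lev, 3, seed = 700 + i + lev * 101)
    event_statistical_features(rec)[["blink_freq"]]
  }
  lo <- sapply(1:50, bf, lev = 1)
  hi <- sapply(1:50, bf, lev = 5)
  expect_gt(auc_score(hi, lo), 0.8)
})

test_that("simulated datasets are balanced on both dimensions", {
  cfg <- small_cfg(npl = 2, dur = 4)
  ds <- simulate_dataset(cfg, seed = 6)
  expect_length(ds$eeg, 10)
  expect_equal(as.integer(table(ds$arousal)), rep(2L, 5))
  expect_equal(as.integer(table(ds$valence)), rep(2L, 5))
  ds2 <- simulate_dataset(cfg, seed = 6)
  expect_identical(ds$eeg[[3]]$data, ds2$eeg[[3]]$data)
  expect_identical(ds$valence, ds2$valence)
})

test_that("labeled structure is recoverable: classifiers beat 20% chance on both dimensions", {
  ex <- feature_dataset_200()   # 40 trials per level
  cv <- cross_validate_dual(ex, repeats = 1, folds = 5, seed = 11)
  for (dim in c("arousal", "valence")) {
    acc <- cv[[dim]]$accuracy
    expect_gt(acc$mean[acc$model == "fused"], 0.2)
    expect_gt(acc$mean[acc$model == "eeg"], 0.2)
  }
})
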