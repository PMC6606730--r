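test_that("Hamming window has the closed-form endpoints, midpoint and symmetry", {
  w <- hamming_window(5)
  expect_equal(w[1], 0.08)
  expect_equal(w[3], 1.0)
  for (N in c(2, 5, 16, 101)) {
    w <- hamming_window(N)
    expect_equal(w, rev(w))
    expect_true(all(w > 0 & w <= 1))
  }
  expect_error(hamming_window(1), ">= 2")
})

test_that("frame blocking yields the floor-formula count and windowed frames", {
  cfg <- small_cfg()
  tr <- simulate_eeg_trial(cfg, 2, 2, seed = 5)  # 2000 samples at 250 Hz
  fs <- frame_block(tr, N = 500, M = 250)
  expect_length(fs$frames, 7)          # floor((2000-500)/250)+1
  expect_true(all(vapply(fs$frames, ncol, integer(1)) == 500))

  one <- frame_block(eeg_trial(tr$data[, 1:500], 250, tr$channel_names),
                     N = 500, M = 250, apply_window = TRUE)
  expect_length(one$frames, 1)
  expect_equal(one$frames[[1]],
               tr$data[, 1:500] * rep(hamming_window(500), each = 30))

  const <- eeg_trial(matrix(1, 30, 20,
                            dimnames = list(emofuse_montage(), NULL)),
                     250, emofuse_montage())
  fw <- frame_block(const, N = 5, M = 0)
  expect_equal(unname(fw$frames[[1]][1, ]), hamming_window(5))

  expect_error(frame_block(tr, N = 5000, M = 0), "exceeds")
  expect_error(frame_block(tr, N = 100, M = 100), "smaller")
})

test_that("frame count formula matches enumeration for random valid designs", {
  set.seed(99)
  for (rep in 1:50) {
    samples <- sample(50:600, 1)
    N <- sample(2:samples, 1)
    M <- sample(0:(N - 1), 1)
    tr <- eeg_trial(matrix(rnorm(30 * samples), 30), 250, emofuse_montage())
    fs <- frame_block(tr, N, M, apply_window = FALSE)
    starts <- seq(1, samples, by = N - M)
    starts <- starts[starts + N - 1 <= samples]  # brute-force enumeration
    expect_length(fs$frames, length(starts))
    expect_length(fs$frames, floor((samples - N) / (N - M)) + 1)
  }
})

test_that("windowing commutes with channel permutation", {
  tr <- small_trial()
  perm <- sample(30)
  trp <- eeg_trial(tr$data[perm, ], tr$sampling_rate_hz,
                   tr$channel_names[perm])
  f1 <- frame_block(tr, 500, 250)
  f2 <- frame_block(trp, 500, 250)
  expect_equal(f2$frames[[3]], f1$frames[[3]][perm, ])
})

test_that("FIR band-pass attenuates stopband, preserves passband, maps zero to zero", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)[-1]
  mk <- function(f) {
    x <- matrix(rep(sin(2 * pi * f * t), 30), 30, byrow = TRUE)
    eeg_trial(x, fs, emofuse_montage())
  }
  rms <- function(x) sqrt(mean(x^2))
  hi <- fir_bandpass(mk(80))
  expect_lt(rms(hi$data[1, ]), 0.5 * rms(mk(80)$data[1, ]))

  # Passband gain from the frequency response of the designed taps.
  taps <- emofuse:::fir_band_taps(32, 0.5, 60, fs)
  H10 <- Mod(sum(taps * exp(-2i * pi * 10 * (seq_along(taps) - 1) / fs)))
  expect_gt(H10, 10^(-3 / 20))
  expect_lt(H10, 10^(3 / 20))

  z <- fir_bandpass(eeg_trial(matrix(0, 30, 1000), fs, emofuse_montage()))
  expect_true(all(z$data == 0))
  expect_error(fir_bandpass(mk(10), low_hz = 50, high_hz = 10), "band edges")
})

test_that("artifact rejection partitions trials by the amplitude threshold", {
  set.seed(3)
  trials <- lapply(1:10, function(i) {
    d <- matrix(rnorm(30 * 100), 30)
    if (i <= 3) d[sample(30, 1), sample(100, 1)] <- 500
    eeg_trial(d, 250, emofuse_montage(), trial_id = paste0("t", i))
  })
  res <- reject_artifact_trials(trials, amplitude_threshold = 100)
  expect_length(res$kept, 7)
  expect_setequal(res$rejected_ids, c("t1", "t2", "t3"))

  all_kept <- reject_artifact_trials(trials, amplitude_threshold = Inf)
  expect_length(all_kept$kept, 10)
  expect_length(all_kept$rejected_ids, 0)

  one <- reject_artifact_trials(trials[3:5], amplitude_threshold = 100)
  expect_identical(one$rejected_ids, "t3")
})

test_that("pupil illumination removal decorrelates a known coupling and spares clean data", {
  set.seed(8)
  n <- 4000
  lum <- rnorm(n)
  s <- rnorm(n)
  lum <- lum / sd(lum); s <- s / sd(s)
  ev <- data.frame(event_type = "fixation", onset_s = 0, duration_s = 1,
                   rotation_deg = 1)
  rec <- eye_record(ev, pupil = s + 0.8 * lum, pupil_rate_hz = 60,
                    luminance = lum)
  expect_gt(abs(cor(rec$pupil, lum)), 0.6)
  cleaned <- remove_pupil_illumination(rec)
  expect_lt(abs(cor(cleaned$pupil, lum)), 0.2)

  # Independent pupil: nearly unchanged.
  rec0 <- eye_record(ev, pupil = s, pupil_rate_hz = 60, luminance = lum)
  cl0 <- remove_pupil_illumination(rec0)
  expect_lt(sqrt(mean((cl0$pupil - s)^2)) / sd(s), 0.05)

  # Constant pupil: untouched.
  recc <- eye_record(ev, pupil = rep(4, n), pupil_rate_hz = 60,
                     luminance = lum)
  expect_equal(remove_pupil_illumination(recc)$pupil, rep(4, n))

  # No luminance: warned no-op.
  recn <- eye_record(ev, pupil = s, pupil_rate_hz = 60)
  expect_warning(out <- remove_pupil_illumination(recn), "luminance")
  expect_equal(out$pupil, s)
})
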