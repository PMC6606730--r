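band <- function(name) {
  b <- eeg_bands()
  b[b$name == name, ]
}

test_that("APS is flat for white noise, concentrated for sinusoids, zero for silence", {
  set.seed(4)
  fs <- 250
  b1 <- list(name = "lo", low_hz = 10, high_hz = 20)
  b2 <- list(name = "hi", low_hz = 30, high_hz = 40)
  r <- replicate(100, {
    x <- rnorm(500) * hamming_window(500)
    band_power_spectrum(x, fs, b1) / band_power_spectrum(x, fs, b2)
  })
  expect_gt(mean(r), 0.5)
  expect_lt(mean(r), 2)

  t <- seq_len(500) / fs
  s <- sin(2 * pi * 10 * t) * hamming_window(500)
  expect_gt(band_power_spectrum(s, fs, band("alpha")),
            10 * band_power_spectrum(s, fs, band("gamma")))
  expect_equal(band_power_spectrum(numeric(500), fs, band("alpha")), 0)
  expect_error(band_power_spectrum(rnorm(500), fs,
                                   list(name = "x", low_hz = 10.1,
                                        high_hz = 10.2)),
               "narrower")
})

test_that("AE matches the mean square of an in-band sinusoid and is 2-homogeneous", {
  fs <- 250
  t <- seq_len(500) / fs
  s <- sin(2 * pi * 10 * t)
  ae <- band_average_energy(s, fs, band("alpha"))
  expect_gt(ae, 0.4)
  expect_lt(ae, 0.6)
  expect_equal(band_average_energy(3 * s, fs, band("alpha")), 9 * ae,
               tolerance = 1e-10)
  expect_equal(band_average_energy(numeric(500), fs, band("beta")), 0)
})

test_that("APS and AE are insensitive to an out-of-band component", {
  fs <- 250
  t <- seq_len(500) / fs
  s <- sin(2 * pi * 10 * t)
  extra <- 2 * sin(2 * pi * 35 * t)  # gamma-band contamination
  w <- hamming_window(500)
  a1 <- band_power_spectrum(s * w, fs, band("alpha"))
  a2 <- band_power_spectrum((s + extra) * w, fs, band("alpha"))
  expect_equal(a2, a1, tolerance = 0.1)
  e1 <- band_average_energy(s, fs, band("alpha"))
  e2 <- band_average_energy(s + extra, fs, band("alpha"))
  expect_equal(e2, e1, tolerance = 0.1)
})

test_that("DAPS vanishes on symmetric frames, negates under left-right swap, tracks amplitude", {
  fs <- 250
  ch <- emofuse_montage()
  pairs <- symmetric_pairs()
  t <- seq_len(500) / fs
  base <- matrix(rnorm(30 * 500), 30, dimnames = list(ch, NULL))
  sym <- base
  sym[pairs$right, ] <- sym[pairs$left, ]  # mirror left onto right
  expect_equal(unname(daps(sym, ch, fs)), rep(0, 60))

  # Swapping left and right channels negates every value.
  swapped <- base
  swapped[pairs$left, ] <- base[pairs$right, ]
  swapped[pairs$right, ] <- base[pairs$left, ]
  expect_equal(daps(swapped, ch, fs), -daps(base, ch, fs),
               ignore_attr = TRUE)

  # Left at twice the amplitude of the same in-band sinusoid: positive DAPS.
  amp <- matrix(0, 30, 500, dimnames = list(ch, NULL))
  amp["F3", ] <- 2 * sin(2 * pi * 10 * t)
  amp["F4", ] <- sin(2 * pi * 10 * t)
  d <- daps(amp, ch, fs)
  expect_gt(d[["DAPS_F3_F4_alpha"]], 0)

  expect_error(daps(base[1:29, ], ch[1:29], fs), "missing")
})

test_that("the assembled EEG vector has the 420-dimensional named layout", {
  fr <- small_trial()$data[, 1:500]
  v <- assemble_eeg_vector(fr, sampling_rate_hz = 250)
  expect_length(v, 420)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_equal(sum(startsWith(names(v), "APS_")), 180)
  expect_equal(sum(startsWith(names(v), "AE_")), 180)
  expect_equal(sum(startsWith(names(v), "DAPS_")), 60)
  expect_identical(attr(v, "modality"), "eeg")

  z <- assemble_eeg_vector(matrix(0, 30, 500,
                                  dimnames = list(emofuse_montage(), NULL)),
                           sampling_rate_hz = 250)
  expect_true(all(z == 0))
  expect_error(assemble_eeg_vector(fr[1:10, ], sampling_rate_hz = 250),
               "30-channel")
})

test_that("trial-level features agree with the mean of per-frame assemblies", {
  tr <- small_trial()
  fast <- eeg_trial_features(tr)
  fset <- frame_block(tr, 500, 250, apply_window = FALSE)
  slow <- rowMeans(vapply(fset$frames, assemble_eeg_vector, fast,
                          sampling_rate_hz = 250))
  expect_identical(names(fast), names(slow))
  aps <- startsWith(names(fast), "APS_") | startsWith(names(fast), "DAPS_")
  expect_equal(fast[aps], slow[aps], tolerance = 1e-10)
  # Band energies differ only by filter edge effects at the frame borders.
  ae <- startsWith(names(fast), "AE_")
  rel <- abs(fast[ae] - slow[ae]) / pmax(abs(slow[ae]), 1e-12)
  expect_lt(stats::median(rel), 0.15)
})

test_that("feature normalization maps |x| to [0, 1] with the min-max formula", {
  x <- cbind(a = c(1, -3, 5), b = c(2, 2, 2), c = c(0.5, 0.2, 0.9))
  expect_warning(y <- normalize_features(x), "constant")
  expect_equal(unname(y[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(y[, "b"]), c(0, 0, 0))
  expect_equal(min(y[, "c"]), 0)
  expect_equal(max(y[, "c"]), 1)
  expect_true(all(y >= 0 & y <= 1))

  # Per-participant grouping normalizes within groups.
  xg <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 1)
  yg <- normalize_features(xg, participants = c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(yg[, 1]), c(0, 0.5, 1, 0, 0.5, 1))
  expect_error(normalize_features(matrix(numeric(0), 0, 2)), "non-empty")
})
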