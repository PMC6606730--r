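# Synthetic multimodal trial generator: class-conditioned EEG oscillations
# with valence-keyed hemispheric asymmetry and arousal-keyed amplitude,
# eye-movement event streams, pupil series with an illumination confound,
# and stimulus rating tables.

#' Default level-dependent eye-movement parameters
#'
#' Event rates are keyed to arousal (blink and saccade rates rise with
#' excitement), fixation gap scaling and mean saccade rotation are keyed to
#' valence, so both emotion dimensions leave a recoverable trace in the eye
#' features.
#'
#' @return Named list of per-level parameter vectors and scalar
#'   distribution parameters.
#' @export
default_eye_params <- function() {
  list(
    blink_rate = c(0.15, 0.20, 0.25, 0.32, 0.40),     # /s, arousal-keyed
    saccade_rate = c(1.0, 1.2, 1.4, 1.7, 2.0),        # /s, arousal-keyed
    fixation_scale = c(1.35, 1.15, 1.00, 0.88, 0.78), # valence-keyed gap scale
    saccade_rot_mean = c(8, 10, 12, 14, 16),          # deg, valence-keyed
    saccade_rot_sd = 4,
    blink_dur_meanlog = log(0.25), blink_dur_sdlog = 0.30,
    saccade_dur_meanlog = log(0.05), saccade_dur_sdlog = 0.25,
    fixation_rot_mean = 1.5, fixation_rot_sd = 0.5    # gaze dispersion, deg
  )
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generator: 55-s trials
#' sampled at 250 Hz on the fixed 30-channel montage, with per-level arousal
#' gains, valence-keyed hemispheric asymmetry of the alpha-range amplitude,
#' level-dependent eye-event statistics, and a pupil-luminance coupling.
#'
#' @param n_trials_per_level Trials per intensity level (default 40, the
#'   per-participant trial count of the emulated protocol).
#' @param sampling_rate_hz EEG sampling rate (default 250 Hz, 2-s frames of
#'   500 samples).
#' @param n_channels Channel count; the montage is fixed at 30.
#' @param trial_duration_s Trial duration (default 55 s stimulus clips).
#' @param seed Base seed for the generator.
#' @param arousal_gain_per_level Multiplicative broadband amplitude gain per
#'   arousal level (length 5, increasing).
#' @param valence_asymmetry_per_level Left-minus-right relative amplitude
#'   offset of the alpha-range bands per valence level (length 5). The
#'   defaults are asymmetric about zero so the level ordering survives the
#'   absolute-value feature normalization.
#' @param eye_rate_params See [default_eye_params()].
#' @param illum_coupling Pupil-luminance coupling coefficient (default 0.8).
#' @param pupil_rate_hz Pupil sampling rate (default 60 Hz).
#' @param band_amplitude_uV Baseline per-band RMS amplitudes.
#' @param noise_sd Additive white sensor-noise standard deviation.
#' @param burst_strength Log-amplitude depth of the slow envelope modulating
#'   each band oscillation; positive values make band amplitudes bursty
#'   (super-Gaussian), as in real EEG, which also makes the channels
#'   separable by ICA.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_trials_per_level = 40,
                       sampling_rate_hz = 250,
                       n_channels = 30,
                       trial_duration_s = 55,
                       seed = 1,
                       arousal_gain_per_level = c(0.8, 1.0, 1.2, 1.45, 1.7),
                       valence_asymmetry_per_level =
                         c(-0.40, -0.15, 0, 0.20, 0.45),
                       eye_rate_params = default_eye_params(),
                       illum_coupling = 0.8,
                       pupil_rate_hz = 60,
                       band_amplitude_uV = c(delta = 8, theta = 6,
                                             slow_alpha = 3, alpha = 5,
                                             beta = 3, gamma = 2),
                       noise_sd = 2,
                       burst_strength = 0.6) {
  abort_if(!is_count(n_trials_per_level), "`n_trials_per_level` must be a positive integer")
  abort_if(!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0,
           "`sampling_rate_hz` must be positive")
  abort_if(n_channels != 30,
           "the montage is fixed at 30 channels (12 symmetric pairs + 6 midline)")
  abort_if(length(arousal_gain_per_level) != 5 ||
             any(arousal_gain_per_level <= 0),
           "`arousal_gain_per_level` must be 5 positive values")
  abort_if(length(valence_asymmetry_per_level) != 5,
           "`valence_asymmetry_per_level` must have length 5")
  for (p in c("blink_rate", "saccade_rate", "fixation_scale",
              "saccade_rot_mean"))
    abort_if(length(eye_rate_params[[p]]) != 5,
             "eye_rate_params$", p, " must have length 5")
  ns <- sampling_rate_hz * trial_duration_s
  abort_if(abs(ns - round(ns)) > 1e-9,
           "sampling_rate_hz * trial_duration_s must be an integer sample count")
  structure(
    list(n_trials_per_level = as.integer(n_trials_per_level),
         sampling_rate_hz = sampling_rate_hz, n_channels = 30L,
         trial_duration_s = trial_duration_s, seed = seed,
         arousal_gain_per_level = arousal_gain_per_level,
         valence_asymmetry_per_level = valence_asymmetry_per_level,
         eye_rate_params = eye_rate_params, illum_coupling = illum_coupling,
         pupil_rate_hz = pupil_rate_hz,
         band_amplitude_uV = band_amplitude_uV, noise_sd = noise_sd,
         burst_strength = burst_strength),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_trials_per_level, "trials/level,",
      x$trial_duration_s, "s @", x$sampling_rate_hz, "Hz, 30 channels\n")
  invisible(x)
}

# Band-limited unit-RMS noise via spectral synthesis (brick-wall band mask
# applied to white noise); deterministic given the RNG state.
band_noise <- function(n, fs, low_hz, high_hz) {
  x <- stats::rnorm(n)
  y <- spectral_band_component(x, fs, low_hz, high_hz)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# Slow lognormal burst envelope with mean ~1: exp(s * z) where z is slow
# (< 1 Hz) unit-variance noise.
burst_envelope <- function(n, fs, strength) {
  if (strength <= 0) return(rep(1, n))
  z <- band_noise(n, fs, 1e-6, min(1, fs / 4))
  e <- exp(strength * z)
  e / mean(e)
}

#' Simulate one class-conditioned EEG trial
#'
#' Each channel is a sum over the six frequency bands of band-limited
#' oscillations (filtered white noise with a slow bursty envelope) plus
#' white sensor noise. The broadband amplitude scales with the arousal
#' level's gain; the alpha-range (alpha and slow alpha) amplitude on the 12
#' symmetric pairs carries a valence-keyed left-minus-right offset
#' (left x (1 + a), right x (1 - a)); midline channels are unaffected.
#' Channels are statistically independent (no volume conduction is
#' modelled).
#'
#' @param cfg A [sim_config()].
#' @param arousal_level,valence_level Integers 1-5.
#' @param seed Seed making the trial reproducible; default derives from
#'   `cfg$seed`.
#' @param trial_id Identifier.
#' @return An [eeg_trial()] with the labels attached.
#' @export
simulate_eeg_trial <- function(cfg, arousal_level, valence_level,
                               seed = cfg$seed, trial_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  a <- check_level(arousal_level, "arousal_level")
  v <- check_level(valence_level, "valence_level")
  fs <- cfg$sampling_rate_hz
  n <- as.integer(round(fs * cfg$trial_duration_s))
  ch <- emofuse_montage()
  bands <- eeg_bands()
  pairs <- symmetric_pairs()
  gain <- cfg$arousal_gain_per_level[a]
  asym <- cfg$valence_asymmetry_per_level[v]
  side <- stats::setNames(rep(1, length(ch)), ch)
  side[pairs$left] <- 1 + asym
  side[pairs$right] <- 1 - asym
  asym_bands <- c("alpha", "slow_alpha")
  data <- with_seed(seed, {
    out <- matrix(0, length(ch), n)
    for (ci in seq_along(ch)) {
      sig <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        amp <- cfg$band_amplitude_uV[[bands$name[b]]] * gain
        if (bands$name[b] %in% asym_bands) amp <- amp * side[[ch[ci]]]
        sig <- sig + amp * band_noise(n, fs, bands$low_hz[b], bands$high_hz[b])
      }
      # One slow vigilance-like envelope per channel modulates the whole
      # oscillatory sum, giving the bursty (super-Gaussian) amplitude
      # statistics of real EEG.
      env <- burst_envelope(n, fs, cfg$burst_strength)
      out[ci, ] <- env * sig + stats::rnorm(n, sd = cfg$noise_sd)
    }
    out
  })
  eeg_trial(data, fs, ch, trial_id = trial_id, arousal = a, valence = v)
}

#' Simulate one eye-movement record
#'
#' Generates a chronologically ordered, non-overlapping event stream:
#' fixations fill the waiting times of two competing exponential clocks
#' (saccades and blinks, rates keyed to arousal), fixation gaps are scaled
#' by the valence level, and event durations are log-normal. The pupil
#' series is a sum of slow oscillatory components in the four pupil bands
#' (lowest-band amplitude keyed to arousal), a luminance regressor scaled by
#' `illum_coupling`, and white noise; the luminance series is returned
#' alongside.
#'
#' @inheritParams simulate_eeg_trial
#' @return An [eye_record()] with a `luminance` component.
#' @export
simulate_eye_record <- function(cfg, arousal_level, valence_level,
                                seed = cfg$seed, trial_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  a <- check_level(arousal_level, "arousal_level")
  v <- check_level(valence_level, "valence_level")
  p <- cfg$eye_rate_params
  T <- cfg$trial_duration_s
  with_seed(seed, {
    type <- character(0); onset <- numeric(0); dur <- numeric(0)
    rot <- numeric(0)
    t <- 0
    while (t < T) {
      gb <- stats::rexp(1, p$blink_rate[a])
      gs <- stats::rexp(1, p$saccade_rate[a])
      fix_dur <- min(gb, gs) * p$fixation_scale[v]
      fix_dur <- min(fix_dur, T - t)
      if (fix_dur > 1e-3) {
        type <- c(type, "fixation"); onset <- c(onset, t)
        dur <- c(dur, fix_dur)
        rot <- c(rot, abs(stats::rnorm(1, p$fixation_rot_mean,
                                       p$fixation_rot_sd)))
      }
      t <- t + fix_dur
      if (t >= T) break
      if (gb < gs) {
        d <- stats::rlnorm(1, p$blink_dur_meanlog, p$blink_dur_sdlog)
        d <- min(d, T - t)
        if (d > 1e-3) {
          type <- c(type, "blink"); onset <- c(onset, t); dur <- c(dur, d)
          rot <- c(rot, NA_real_)
        }
        t <- t + d
      } else {
        d <- stats::rlnorm(1, p$saccade_dur_meanlog, p$saccade_dur_sdlog)
        d <- min(d, T - t)
        if (d > 1e-3) {
          type <- c(type, "saccade"); onset <- c(onset, t); dur <- c(dur, d)
          rot <- c(rot, abs(stats::rnorm(1, p$saccade_rot_mean[v],
                                         p$saccade_rot_sd)))
        }
        t <- t + d
      }
    }
    events <- data.frame(event_type = type, onset_s = onset,
                         duration_s = dur, rotation_deg = rot,
                         stringsAsFactors = FALSE)

    prate <- cfg$pupil_rate_hz
    np <- as.integer(round(prate * T))
    pb <- pupil_bands()
    pupil <- rep(4, np)  # baseline diameter, mm
    for (b in seq_len(nrow(pb))) {
      amp <- if (pb$low_hz[b] <= 0.02) 0.25 + 0.05 * a else 0.10
      pupil <- pupil + amp * band_noise(np, prate, pb$low_hz[b], pb$high_hz[b])
    }
    lum <- band_noise(np, prate, 1e-6, 0.1)  # slow illumination drift
    pupil <- pupil + cfg$illum_coupling * lum + stats::rnorm(np, sd = 0.05)
    eye_record(events, pupil, prate, luminance = lum,
               trial_id = trial_id, duration_s = T)
  })
}

#' Simulate a stimulus rating table
#'
#' Per-clip rating samples on both emotion dimensions with nonzero
#' dispersion, constructed so the normalized scores (mean / population SD)
#' span the anchor ranges used for training-stimulus selection
#' (at least \[-2.5, 2.5\] on arousal, and reaching -1.5 and 3 on valence).
#' If sampling noise leaves an extreme uncovered, the extreme clips' target
#' scores are pushed outward and regenerated.
#'
#' @param n_clips Number of clips (at least 40; default 120).
#' @param seed Seed.
#' @param n_raters Ratings per clip per dimension (default 15).
#' @return Object of class `rating_table`: list with `clip_id`,
#'   `arousal` and `valence` rating matrices (clips x raters).
#' @export
simulate_rating_table <- function(n_clips = 120, seed = 1, n_raters = 15) {
  abort_if(!is_count(n_clips) || n_clips < 40, "`n_clips` must be >= 40")
  with_seed(seed, {
    target_a <- stats::runif(n_clips, -2.8, 2.8)
    target_v <- stats::runif(n_clips, -1.8, 3.3)
    # Pin the extremes so the anchor ranges are always reachable.
    target_a[1:2] <- c(-2.8, 2.8)
    target_v[3:4] <- c(-1.7, 3.2)
    gen <- function(targets) {
      s <- stats::runif(n_clips, 0.8, 1.3)
      z <- matrix(stats::rnorm(n_clips * n_raters), n_clips)
      sweep(sweep(z, 1L, s, "*"), 1L, targets * s, "+")
    }
    score_of <- function(r) apply(r, 1L, function(x) mean(x) / pop_sd(x))
    ra <- gen(target_a)
    for (i in 1:10) {
      sc <- score_of(ra)
      if (min(sc) <= -2.5 && max(sc) >= 2.5) break
      if (min(sc) > -2.5) target_a[1] <- target_a[1] - 0.5
      if (max(sc) < 2.5) target_a[2] <- target_a[2] + 0.5
      ra <- gen(target_a)
    }
    rv <- gen(target_v)
    structure(
      list(clip_id = sprintf("clip%03d", seq_len(n_clips)),
           arousal = ra, valence = rv),
      class = "rating_table"
    )
  })
}

#' @export
print.rating_table <- function(x, ...) {
  cat("Stimulus rating table:", length(x$clip_id), "clips x",
      ncol(x$arousal), "raters per dimension\n")
  invisible(x)
}

#' Simulate a labeled multimodal dataset
#'
#' Generates `5 * n_trials_per_level` trials balanced over both dimensions:
#' arousal levels cycle 1-5 and valence levels are a shuffled balanced
#' assignment, so each dimension has equally many trials per level. Each
#' trial gets one EEG trial and one eye record with matching labels.
#'
#' @param cfg A [sim_config()].
#' @param seed Base seed (default `cfg$seed`); trial t derives its own
#'   seeds from it.
#' @return Object of class `sim_dataset`: list with `eeg` (list of
#'   [eeg_trial()]), `eye` (list of [eye_record()]), `arousal`, `valence`,
#'   `trial_id`, `cfg`.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  npl <- cfg$n_trials_per_level
  ntr <- 5L * npl
  base <- as.integer(seed %% 1e6)
  arousal <- rep(1:5, npl)
  valence <- with_seed(base, sample(rep(1:5, npl)))
  ids <- sprintf("trial%03d", seq_len(ntr))
  eeg <- vector("list", ntr)
  eye <- vector("list", ntr)
  for (t in seq_len(ntr)) {
    eeg[[t]] <- simulate_eeg_trial(cfg, arousal[t], valence[t],
                                   seed = base + t * 1000L + 1L,
                                   trial_id = ids[t])
    eye[[t]] <- simulate_eye_record(cfg, arousal[t], valence[t],
                                    seed = base + t * 1000L + 2L,
                                    trial_id = ids[t])
  }
  structure(list(eeg = eeg, eye = eye, arousal = arousal, valence = valence,
                 trial_id = ids, cfg = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated multimodal dataset:", length(x$trial_id), "trials (",
      x$cfg$n_trials_per_level, "per level ),", x$cfg$trial_duration_s,
      "s each\n")
  invisible(x)
}

#' Extract per-trial feature matrices from a simulated dataset
#'
#' Runs the standard pipeline on every trial: FIR band-pass filtering
#' (0.5-60 Hz), frame blocking with Hamming windows and the 420-dimensional
#' EEG feature vector averaged over frames; the 20-dimensional eye-movement
#' vector from the event stream. Features are returned unnormalized (see
#' [normalize_features()] / [cross_validate()]).
#'
#' @param dataset A [simulate_dataset()] result.
#' @param N,M Frame length and overlap in samples.
#' @param filter_order FIR order of the broadband pre-filter.
#' @return List with `features` (named list of matrices `eeg`
#'   (trials x 420) and `eye` (trials x 20)), `arousal`, `valence`,
#'   `trial_id`.
#' @export
extract_dataset_features <- function(dataset, N = 500, M = 250,
                                     filter_order = 32) {
  stopifnot(inherits(dataset, "sim_dataset"))
  ntr <- length(dataset$trial_id)
  eegf <- NULL
  eyef <- NULL
  for (t in seq_len(ntr)) {
    tr <- fir_bandpass(dataset$eeg[[t]], order = filter_order)
    fv <- eeg_trial_features(tr, N = N, M = M)
    ev <- assemble_eye_vector(dataset$eye[[t]])
    if (is.null(eegf)) {
      eegf <- matrix(0, ntr, length(fv), dimnames = list(NULL, names(fv)))
      eyef <- matrix(0, ntr, length(ev), dimnames = list(NULL, names(ev)))
    }
    eegf[t, ] <- fv
    eyef[t, ] <- ev
  }
  list(features = list(eeg = eegf, eye = eyef),
       arousal = dataset$arousal, valence = dataset$valence,
       trial_id = dataset$trial_id)
}
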