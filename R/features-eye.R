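# Eye-movement features: event-class statistics, event statistics, the
# 20-dimensional per-trial vector, and optional pupil spectral features.

events_of <- function(record, type) {
  ev <- record$events
  ev[ev$event_type == type, , drop = FALSE]
}

#' Duration/rotation statistics per event class
#'
#' Seven features: blink mean and standard deviation of duration; saccade
#' mean, standard deviation of duration and mean rotation angle; fixation
#' mean and standard deviation of duration. Population (divide-by-n)
#' standard deviations are used, so a single event yields 0. Event types
#' with no events yield 0 for their statistics with a warning.
#'
#' @param record An [eye_record()] object.
#' @return Named numeric vector of length 7.
#' @export
event_class_stats <- function(record) {
  stopifnot(inherits(record, "eye_record"))
  stat2 <- function(type) {
    d <- events_of(record, type)$duration_s
    if (length(d) == 0) {
      warning("no ", type, " events; statistics set to 0")
      c(0, 0)
    } else c(mean(d), pop_sd(d))
  }
  sac <- events_of(record, "saccade")
  sac_rot <- if (nrow(sac) == 0) {
    0
  } else mean(sac$rotation_deg, na.rm = TRUE)
  feature_vector(
    c(stat2("blink"), stat2("saccade"), sac_rot, stat2("fixation")),
    c("blink_dur_mean", "blink_dur_sd",
      "saccade_dur_mean", "saccade_dur_sd", "saccade_rot_mean",
      "fixation_dur_mean", "fixation_dur_sd"),
    modality = "eye", trial_id = record$trial_id
  )
}

#' Event frequencies and extremal statistics
#'
#' Thirteen features: frequencies (events per second) of saccades, blinks
#' and fixations, then for fixations and saccades in turn the duration
#' maximum, average and minimum and the rotation-angle maximum and average.
#' An empty record yields all zeros.
#'
#' @param record An [eye_record()] object.
#' @param trial_duration_s Trial duration in seconds; defaults to the
#'   record's own duration.
#' @return Named numeric vector of length 13.
#' @export
event_statistical_features <- function(record,
                                       trial_duration_s = record$duration_s) {
  stopifnot(inherits(record, "eye_record"))
  abort_if(!is.numeric(trial_duration_s) || trial_duration_s <= 0,
           "`trial_duration_s` must be positive")
  freq <- function(type) nrow(events_of(record, type)) / trial_duration_s
  stats5 <- function(type) {
    ev <- events_of(record, type)
    if (nrow(ev) == 0) return(rep(0, 5))
    rot <- ev$rotation_deg[is.finite(ev$rotation_deg)]
    if (length(rot) == 0) rot <- 0
    c(max(ev$duration_s), mean(ev$duration_s), min(ev$duration_s),
      max(rot), mean(rot))
  }
  nm5 <- c("dur_max", "dur_avg", "dur_min", "rot_max", "rot_avg")
  feature_vector(
    c(freq("saccade"), freq("blink"), freq("fixation"),
      stats5("fixation"), stats5("saccade")),
    c("saccade_freq", "blink_freq", "fixation_freq",
      paste0("fixation_", nm5), paste0("saccade_", nm5)),
    modality = "eye", trial_id = record$trial_id
  )
}

#' Assemble the per-trial eye-movement feature vector
#'
#' Concatenates [event_class_stats()] (7 features) and
#' [event_statistical_features()] (13 features) into the 20-dimensional
#' eye-movement vector. Pupil spectral features (8 more) can be appended
#' with `include_pupil = TRUE`; the default follows the 20-dimension layout.
#'
#' @param record An [eye_record()] object.
#' @param trial_duration_s Trial duration in seconds (defaults to the
#'   record's duration).
#' @param include_pupil If `TRUE`, append [pupil_spectral_features()].
#' @return Named numeric vector of length 20 (28 with pupil features).
#' @export
assemble_eye_vector <- function(record, trial_duration_s = record$duration_s,
                                include_pupil = FALSE) {
  v <- c(event_class_stats(record),
         event_statistical_features(record, trial_duration_s))
  if (include_pupil) v <- c(v, pupil_spectral_features(record))
  feature_vector(v, names(v), modality = "eye", trial_id = record$trial_id)
}

#' Pupil frequency bands
#'
#' The four low-frequency bands used for pupil spectral features, highest
#' first: 0.6-1.0, 0.4-0.6, 0.2-0.4 and 0.01-0.2 Hz.
#'
#' @return Data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
pupil_bands <- function() {
  data.frame(
    name    = c("b0.6_1.0", "b0.4_0.6", "b0.2_0.4", "b0.01_0.2"),
    low_hz  = c(0.6, 0.4, 0.2, 0.01),
    high_hz = c(1.0, 0.6, 0.4, 0.2),
    stringsAsFactors = FALSE
  )
}

# Isolate a frequency band by zeroing FFT bins outside it (brick-wall),
# appropriate for the very low pupil bands where FIR filters are impractical.
spectral_band_component <- function(x, fs, low_hz, high_hz) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1L) * fs / n
  fmag <- pmin(f, fs - f)
  keep <- fmag >= low_hz & fmag <= high_hz
  Re(stats::fft(X * keep, inverse = TRUE)) / n
}

#' Pupil spectral features (PSD mean and differential entropy per band)
#'
#' For each of the four pupil bands: the mean periodogram PSD over the band
#' and the Gaussian-form differential entropy
#' \eqn{DE = 0.5 \log(2\pi e\, \sigma^2)} of the band-isolated component,
#' giving 8 features. A zero-variance band returns `de_floor` with a warning.
#'
#' @param record An [eye_record()] object with a pupil series.
#' @param bands Band definitions; default [pupil_bands()].
#' @param de_floor Differential-entropy floor for degenerate (zero-variance)
#'   bands; default -20 nats.
#' @return Named numeric vector of length 8.
#' @export
pupil_spectral_features <- function(record, bands = pupil_bands(),
                                    de_floor = -20) {
  stopifnot(inherits(record, "eye_record"))
  x <- record$pupil
  fs <- record$pupil_rate_hz
  abort_if(length(x) < 4, "pupil series too short")
  res <- fs / length(x)
  abort_if(res > min(bands$high_hz - bands$low_hz),
           "pupil series too short: frequency resolution ", format(res),
           " Hz leaves a band without bins")
  pg <- periodogram_psd(x - mean(x), fs)
  out <- numeric(0)
  nm <- character(0)
  for (b in seq_len(nrow(bands))) {
    sel <- pg$freq >= bands$low_hz[b] & pg$freq <= bands$high_hz[b]
    abort_if(!any(sel), "band '", bands$name[b], "' contains no frequency bin")
    comp <- spectral_band_component(x, fs, bands$low_hz[b], bands$high_hz[b])
    v <- mean(comp^2)
    de <- if (v <= .Machine$double.eps) {
      warning("zero variance in pupil band '", bands$name[b],
              "'; differential entropy floored")
      de_floor
    } else 0.5 * log(2 * pi * exp(1) * v)
    out <- c(out, mean(pg$psd[sel]), de)
    nm <- c(nm, paste0("pupil_psd_", bands$name[b]),
            paste0("pupil_de_", bands$name[b]))
  }
  feature_vector(out, nm, modality = "eye", trial_id = record$trial_id)
}
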