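# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulators are reproducible without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(paste0(...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

check_level <- function(level, what) {
  abort_if(!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
             level != round(level) || level < 1 || level > 5,
           what, " must be a single integer between 1 and 5, got ",
           deparse(substitute(level)), " = ", format(level))
  as.integer(level)
}

# Population (divide-by-n) standard deviation; 0 for a single value.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Standard 30-channel 10-20 montage
#'
#' Channel names used throughout the package, in recording order. The montage
#' contains the 12 left/right symmetric pairs required by the hemispheric
#' asymmetry (DAPS) features plus six midline electrodes.
#'
#' @return Character vector of 30 channel labels.
#' @seealso [symmetric_pairs()]
#' @export
emofuse_montage <- function() {
  c("FP1", "FP2",
    "F7", "F3", "FZ", "F4", "F8",
    "FT7", "FC3", "FCZ", "FC4", "FT8",
    "T3", "C3", "CZ", "C4", "T4",
    "TP7", "CP3", "CPZ", "CP4", "TP8",
    "T5", "P3", "PZ", "P4", "T6",
    "O1", "OZ", "O2")
}

#' Symmetric electrode pairs for hemispheric asymmetry features
#'
#' The 12 left/right electrode pairs over which differential band power
#' (DAPS) is computed.
#'
#' @return A data frame with character columns `left` and `right`, 12 rows.
#' @export
symmetric_pairs <- function() {
  data.frame(
    left  = c("FP1", "F7", "F3", "FT7", "FC3", "T3", "C3", "TP7", "CP3",
              "T5", "P3", "O1"),
    right = c("FP2", "F8", "F4", "FT8", "FC4", "T4", "C4", "TP8", "CP4",
              "T6", "P4", "O2"),
    stringsAsFactors = FALSE
  )
}

#' EEG frequency band definitions
#'
#' The six canonical bands used for spectral features: delta (0.5-4 Hz),
#' theta (4-8 Hz), slow alpha (8-10 Hz), alpha (8-12 Hz), beta (12-30 Hz)
#' and gamma (30-40 Hz).
#'
#' @return Data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    name    = c("delta", "theta", "slow_alpha", "alpha", "beta", "gamma"),
    low_hz  = c(0.5, 4, 8, 8, 12, 30),
    high_hz = c(4, 8, 10, 12, 30, 40),
    stringsAsFactors = FALSE
  )
}

# Bands entering DAPS: all except slow alpha.
daps_bands <- function() {
  b <- eeg_bands()
  b[b$name != "slow_alpha", , drop = FALSE]
}

#' Construct an EEG trial object
#'
#' Container for one multichannel EEG trial: a channels x samples matrix with
#' a sampling rate, ordered 10-20 channel names and optional intensity labels.
#'
#' @param data Numeric matrix, channels x samples, all values finite.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param channel_names Character vector, one label per row of `data`.
#' @param trial_id Identifier for the trial.
#' @param arousal,valence Optional intensity labels (integers 1-5).
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, sampling_rate_hz, channel_names,
                      trial_id = "trial", arousal = NA, valence = NA) {
  abort_if(!is.matrix(data) || !is.numeric(data), "`data` must be a numeric matrix")
  abort_if(any(!is.finite(data)), "EEG trial contains non-finite values")
  abort_if(length(channel_names) != nrow(data),
           "channel count (", nrow(data), ") does not match channel_names (",
           length(channel_names), ")")
  abort_if(!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0,
           "`sampling_rate_hz` must be positive")
  rownames(data) <- channel_names
  structure(
    list(data = data, sampling_rate_hz = sampling_rate_hz,
         channel_names = channel_names, trial_id = trial_id,
         arousal = arousal, valence = valence),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat("EEG trial", x$trial_id, ":", nrow(x$data), "channels x",
      ncol(x$data), "samples @", x$sampling_rate_hz, "Hz\n")
  if (!is.na(x$arousal) || !is.na(x$valence))
    cat("  labels: arousal", x$arousal, "/ valence", x$valence, "\n")
  invisible(x)
}

#' Construct an eye-movement record
#'
#' Container for one trial's eye-movement data: an ordered event stream
#' (fixations, saccades, blinks) plus a pupil-diameter series and, optionally,
#' an aligned luminance regressor.
#'
#' @param events Data frame with columns `event_type` (one of "fixation",
#'   "saccade", "blink"), `onset_s`, `duration_s`, `rotation_deg` (NA where
#'   not applicable). Onsets must be nondecreasing and durations positive.
#' @param pupil Numeric vector, pupil diameter series.
#' @param pupil_rate_hz Sampling rate of the pupil series.
#' @param luminance Optional numeric vector aligned with `pupil`.
#' @param trial_id Identifier.
#' @param duration_s Trial duration in seconds.
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(events, pupil, pupil_rate_hz, luminance = NULL,
                       trial_id = "trial", duration_s = NULL) {
  need <- c("event_type", "onset_s", "duration_s", "rotation_deg")
  abort_if(!is.data.frame(events) || !all(need %in% names(events)),
           "`events` must have columns ", paste(need, collapse = ", "))
  abort_if(nrow(events) > 0 && any(diff(events$onset_s) < 0),
           "event onsets must be nondecreasing")
  abort_if(nrow(events) > 0 && any(events$duration_s <= 0),
           "event durations must be positive")
  bad <- setdiff(unique(events$event_type), c("fixation", "saccade", "blink"))
  abort_if(length(bad) > 0, "unknown event types: ", paste(bad, collapse = ", "))
  if (!is.null(luminance))
    abort_if(length(luminance) != length(pupil),
             "pupil and luminance series must be aligned and of equal length")
  if (is.null(duration_s))
    duration_s <- if (nrow(events)) max(events$onset_s + events$duration_s) else
      length(pupil) / pupil_rate_hz
  structure(
    list(events = events, pupil = pupil, pupil_rate_hz = pupil_rate_hz,
         luminance = luminance, trial_id = trial_id, duration_s = duration_s),
    class = "eye_record"
  )
}

#' @export
print.eye_record <- function(x, ...) {
  tab <- table(factor(x$events$event_type,
                      levels = c("fixation", "saccade", "blink")))
  cat("Eye record", x$trial_id, ":", x$duration_s, "s,",
      paste(tab, names(tab), collapse = ", "), "\n")
  cat("  pupil:", length(x$pupil), "samples @", x$pupil_rate_hz, "Hz",
      if (is.null(x$luminance)) "(no luminance)" else "(with luminance)", "\n")
  invisible(x)
}

# Named feature vector with a modality tag.
feature_vector <- function(values, names, modality, trial_id = NA) {
  abort_if(length(values) != length(names), "values/names length mismatch")
  v <- as.numeric(values)
  names(v) <- names
  attr(v, "modality") <- modality
  attr(v, "trial_id") <- trial_id
  v
}
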