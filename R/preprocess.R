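# Preprocessing: frame blocking, windowing, FIR band-pass filtering,
# artifact-trial rejection, and pupil illumination removal.

#' Hamming window
#'
#' Returns the N-point Hamming window
#' \eqn{\omega(n) = 0.54 - 0.46\cos(2\pi n/(N-1))}, \eqn{0 \le n \le N-1},
#' used to taper each EEG frame before spectral estimation.
#'
#' @param N Window length in samples, at least 2.
#' @return Numeric vector of length `N`.
#' @export
hamming_window <- function(N) {
  abort_if(!is_count(N) || N < 2, "`N` must be an integer >= 2")
  n <- seq_len(N) - 1
  0.54 - 0.46 * cos(2 * pi * n / (N - 1))
}

#' Split an EEG trial into overlapping frames
#'
#' Blocks a trial into frames of `N` samples advanced by `N - M` samples
#' (overlap `M`), optionally tapering each channel of each frame with a
#' Hamming window. Trailing samples that do not fill a complete frame are
#' dropped, so the frame count is `floor((samples - N) / (N - M)) + 1`.
#'
#' @param trial An [eeg_trial()] object.
#' @param N Frame length in samples (default 500, i.e. 2 s at 250 Hz).
#' @param M Overlap in samples (default 250, half the frame).
#' @param apply_window If `TRUE` (default), multiply each channel of each
#'   frame elementwise by [hamming_window()].
#' @return An object of class `frame_set`: a list with elements `frames`
#'   (list of channels x N matrices), `N`, `M`, `channel_names`,
#'   `sampling_rate_hz` and `source_trial_id`.
#' @export
frame_block <- function(trial, N = 500, M = 250, apply_window = TRUE) {
  stopifnot(inherits(trial, "eeg_trial"))
  samples <- ncol(trial$data)
  abort_if(!is_count(N), "`N` must be a positive integer")
  abort_if(!is.numeric(M) || length(M) != 1 || M != round(M) || M < 0,
           "`M` must be a nonnegative integer")
  abort_if(M >= N, "overlap M must be smaller than frame length N")
  abort_if(N > samples, "frame length N (", N, ") exceeds trial length (",
           samples, ")")
  step <- N - M
  starts <- seq.int(1L, samples - N + 1L, by = step)
  w <- if (apply_window) hamming_window(N) else NULL
  frames <- lapply(starts, function(s) {
    fr <- trial$data[, s:(s + N - 1L), drop = FALSE]
    if (!is.null(w)) fr <- fr * rep(w, each = nrow(fr))
    fr
  })
  structure(
    list(frames = frames, N = as.integer(N), M = as.integer(M),
         starts = starts, channel_names = trial$channel_names,
         sampling_rate_hz = trial$sampling_rate_hz,
         source_trial_id = trial$trial_id),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  cat("Frame set:", length(x$frames), "frames of", x$N, "samples (overlap",
      x$M, ") from trial", x$source_trial_id, "\n")
  invisible(x)
}

# Linear-phase FIR band-pass taps (windowed sinc, Hamming). `order` taps + 1
# coefficients; even order keeps an integer group delay.
fir_band_taps <- function(order, low_hz, high_hz, sampling_rate_hz) {
  nyq <- sampling_rate_hz / 2
  abort_if(!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0 ||
             high_hz <= low_hz || high_hz >= nyq,
           "invalid band edges: need 0 < low < high < Nyquist (", nyq, " Hz)")
  abort_if(!is_count(order) || order < 2, "`order` must be an integer >= 2")
  if (order %% 2 == 1) order <- order + 1L  # keep integer group delay
  as.numeric(signal::fir1(order, c(low_hz, high_hz) / nyq, type = "pass"))
}

# Apply linear-phase FIR taps to a vector with reflection padding and group
# delay compensation, so the output is time-aligned with the input.
fir_apply <- function(x, taps) {
  nt <- length(taps)
  if (nt >= length(x)) {
    pad <- length(x) - 1L
  } else {
    pad <- nt
  }
  d <- (nt - 1L) %/% 2L
  n <- length(x)
  xe <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[n] - rev(x[n - seq_len(pad)]))
  y <- stats::filter(xe, taps, method = "convolution", sides = 1L)
  as.numeric(y[pad + d + seq_len(n)])
}

#' Linear-phase FIR band-pass filter for EEG trials
#'
#' Filters every channel of a trial with a linear-phase finite impulse
#' response band-pass filter (windowed-sinc design with Hamming taps),
#' default 32nd order with 0.5-60 Hz edges. The group delay is compensated
#' so the output stays aligned with the input.
#'
#' @param trial An [eeg_trial()] object.
#' @param order Filter order (number of taps minus one); default 32.
#' @param low_hz,high_hz Band edges in Hz; `high_hz` must be below Nyquist.
#' @return The filtered [eeg_trial()].
#' @export
fir_bandpass <- function(trial, order = 32, low_hz = 0.5, high_hz = 60) {
  stopifnot(inherits(trial, "eeg_trial"))
  taps <- fir_band_taps(order, low_hz, high_hz, trial$sampling_rate_hz)
  out <- t(apply(trial$data, 1L, fir_apply, taps = taps))
  dimnames(out) <- dimnames(trial$data)
  trial$data <- out
  trial
}

#' Reject trials exceeding an amplitude threshold
#'
#' Automated stand-in for manual artifact screening: a trial is rejected iff
#' any sample's absolute value exceeds `amplitude_threshold`.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param amplitude_threshold Positive rejection threshold (same units as the
#'   trial data; default 100).
#' @return List with elements `kept` (list of trials) and `rejected_ids`
#'   (character vector of trial ids).
#' @export
reject_artifact_trials <- function(trials, amplitude_threshold = 100) {
  abort_if(!is.numeric(amplitude_threshold) || amplitude_threshold <= 0,
           "`amplitude_threshold` must be positive")
  bad <- vapply(trials, function(tr) max(abs(tr$data)) > amplitude_threshold,
                logical(1))
  list(
    kept = trials[!bad],
    rejected_ids = vapply(trials[bad], function(tr) as.character(tr$trial_id),
                          character(1))
  )
}

#' Remove the illumination-driven component from a pupil series
#'
#' Pupil diameter reflects both emotional state and light reflex. Given an
#' aligned luminance regressor, the illumination-driven component is
#' identified as the principal direction of the standardized
#' (pupil, luminance) representation aligned with luminance, and its pupil
#' contribution is removed by least-squares projection onto the luminance
#' series (the exact two-series form of the estimate). The cleaned pupil is
#' uncorrelated with luminance.
#'
#' @param record An [eye_record()] with a `luminance` series.
#' @param n_components Number of components to remove; only 1 is meaningful
#'   for the two-series representation and other values are ignored with a
#'   warning.
#' @return The record with the cleaned pupil series; attributes
#'   `illum_r_before` and `illum_r_after` store the pupil-luminance
#'   correlations.
#' @export
remove_pupil_illumination <- function(record, n_components = 1) {
  stopifnot(inherits(record, "eye_record"))
  if (is.null(record$luminance)) {
    warning("no luminance regressor available; pupil left unchanged")
    return(record)
  }
  if (!identical(as.integer(n_components), 1L))
    warning("only one illumination component is removable from a single ",
            "luminance regressor; using n_components = 1")
  p <- record$pupil
  l <- record$luminance
  vl <- stats::var(l)
  if (!is.finite(vl) || vl == 0 || stats::var(p) == 0) return(record)
  r_before <- stats::cor(p, l)
  beta <- stats::cov(p, l) / vl
  cleaned <- p - beta * (l - mean(l))
  r_after <- if (stats::var(cleaned) > 0) stats::cor(cleaned, l) else 0
  record$pupil <- cleaned
  attr(record, "illum_r_before") <- r_before
  attr(record, "illum_r_after") <- r_after
  record
}
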