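# Time-frequency EEG features: band power spectra (APS), band energies (AE),
# hemispheric asymmetry (DAPS), the 420-dimensional per-frame vector, and
# feature normalization.

# One-sided periodogram PSD of a (pre-windowed) frame channel.
periodogram_psd <- function(x, sampling_rate_hz) {
  n <- length(x)
  X <- stats::fft(x)
  half <- n %/% 2L + 1L
  p <- (Mod(X[seq_len(half)])^2) / (sampling_rate_hz * n)
  sc <- rep(2, half)
  sc[1L] <- 1
  if (n %% 2L == 0L) sc[half] <- 1
  list(freq = (seq_len(half) - 1L) * sampling_rate_hz / n, psd = p * sc)
}

check_band <- function(band, sampling_rate_hz) {
  abort_if(is.null(band$low_hz) || is.null(band$high_hz) ||
             band$low_hz >= band$high_hz,
           "band must have low_hz < high_hz")
  abort_if(band$high_hz > sampling_rate_hz / 2,
           "band '", band$name, "' exceeds the Nyquist frequency")
  invisible(band)
}

#' Average power spectral density over a frequency band (APS)
#'
#' Mean of the single-frame periodogram PSD over the frequency bins falling
#' inside the band. The frame channel is expected to be Hamming-windowed
#' already (see [frame_block()]).
#'
#' @param frame_channel Numeric vector, one channel of one frame.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param band A one-row data frame or list with `name`, `low_hz`, `high_hz`
#'   (see [eeg_bands()]).
#' @return Nonnegative scalar.
#' @export
band_power_spectrum <- function(frame_channel, sampling_rate_hz, band) {
  check_band(band, sampling_rate_hz)
  pg <- periodogram_psd(frame_channel, sampling_rate_hz)
  sel <- pg$freq >= band$low_hz & pg$freq <= band$high_hz
  abort_if(!any(sel), "band '", band$name,
           "' is narrower than the spectral resolution (",
           format(sampling_rate_hz / length(frame_channel)), " Hz)")
  mean(pg$psd[sel])
}

#' Average energy of a band-filtered frame (AE)
#'
#' Mean squared amplitude of the frame channel after band-pass filtering
#' (windowed-sinc FIR). The frame is filtered unwindowed; energy is taken in
#' the time domain.
#'
#' @inheritParams band_power_spectrum
#' @param order FIR order for the band filter; capped so the filter stays
#'   shorter than half the frame.
#' @return Nonnegative scalar.
#' @export
band_average_energy <- function(frame_channel, sampling_rate_hz, band,
                                order = 128) {
  check_band(band, sampling_rate_hz)
  abort_if(sampling_rate_hz / length(frame_channel) > band$high_hz - band$low_hz,
           "band '", band$name, "' is narrower than the spectral resolution")
  order <- min(order, 2L * (length(frame_channel) %/% 4L))
  taps <- fir_band_taps(order, band$low_hz, band$high_hz, sampling_rate_hz)
  y <- fir_apply(frame_channel, taps)
  mean(y^2)
}

#' Differential average power spectrum over symmetric pairs (DAPS)
#'
#' For each of the 12 symmetric electrode pairs and each of the five bands
#' (slow alpha excluded), the signed left-minus-right APS difference, a
#' hemispheric-asymmetry feature informative for valence. Output is ordered
#' pair-major, then band.
#'
#' @param frame Numeric matrix, channels x samples (pre-windowed).
#' @param channel_names Channel labels for the rows of `frame`.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param pairs Data frame of `left`/`right` labels; default
#'   [symmetric_pairs()].
#' @param bands Band definitions; default the five DAPS bands.
#' @return Named numeric vector of length `nrow(pairs) * nrow(bands)`
#'   (60 by default).
#' @export
daps <- function(frame, channel_names = rownames(frame), sampling_rate_hz,
                 pairs = symmetric_pairs(), bands = NULL) {
  if (is.null(bands)) bands <- daps_bands()
  missing <- setdiff(unique(c(pairs$left, pairs$right)), channel_names)
  abort_if(length(missing) > 0,
           "channels missing from the montage: ", paste(missing, collapse = ", "))
  aps_for <- function(ch) {
    x <- frame[match(ch, channel_names), ]
    vapply(seq_len(nrow(bands)), function(b)
      band_power_spectrum(x, sampling_rate_hz, bands[b, ]), numeric(1))
  }
  out <- numeric(0)
  nm <- character(0)
  for (p in seq_len(nrow(pairs))) {
    d <- aps_for(pairs$left[p]) - aps_for(pairs$right[p])
    out <- c(out, d)
    nm <- c(nm, paste0("DAPS_", pairs$left[p], "_", pairs$right[p], "_",
                       bands$name))
  }
  names(out) <- nm
  out
}

#' Assemble the 420-dimensional EEG feature vector for one frame
#'
#' Concatenates, for a 30-channel frame, the average power spectral density
#' (APS, 30 channels x 6 bands), the average band energy (AE, 30 x 6) and the
#' differential APS over the 12 symmetric pairs and 5 bands (DAPS, 12 x 5),
#' giving 30*6 + 30*6 + 12*5 = 420 named features. The Hamming window is
#' applied internally for the spectral features; band energies are computed
#' on the raw frame.
#'
#' @param frame Numeric matrix, 30 channels x N samples (unwindowed).
#' @param channel_names Channel labels for the rows; default the rownames.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param bands Band definitions; default [eeg_bands()].
#' @param pairs Symmetric pairs; default [symmetric_pairs()].
#' @return Named numeric vector of length 420 with attribute
#'   `modality = "eeg"`.
#' @export
assemble_eeg_vector <- function(frame, channel_names = rownames(frame),
                                sampling_rate_hz, bands = eeg_bands(),
                                pairs = symmetric_pairs()) {
  abort_if(nrow(frame) != 30, "expected a 30-channel frame, got ",
           nrow(frame), " channels")
  abort_if(is.null(channel_names), "channel names are required")
  w <- hamming_window(ncol(frame))
  fw <- frame * rep(w, each = nrow(frame))
  nb <- nrow(bands)
  aps <- matrix(0, nrow(frame), nb)
  ae <- matrix(0, nrow(frame), nb)
  for (ch in seq_len(nrow(frame))) {
    for (b in seq_len(nb)) {
      aps[ch, b] <- band_power_spectrum(fw[ch, ], sampling_rate_hz, bands[b, ])
      ae[ch, b] <- band_average_energy(frame[ch, ], sampling_rate_hz, bands[b, ])
    }
  }
  nm_grid <- as.vector(t(outer(channel_names, bands$name, paste, sep = "_")))
  d <- daps(fw, channel_names, sampling_rate_hz, pairs)
  feature_vector(
    c(as.vector(t(aps)), as.vector(t(ae)), d),
    c(paste0("APS_", nm_grid), paste0("AE_", nm_grid), names(d)),
    modality = "eeg"
  )
}

#' Per-trial EEG features (mean over frames)
#'
#' Extracts the 420-dimensional feature vector for every frame of a trial and
#' averages over frames, yielding one vector per trial. Band energies are
#' computed by filtering the full trial once per band and averaging squared
#' samples per frame, which avoids per-frame filter transients; the result
#' agrees with the frame-wise operators up to edge effects.
#'
#' @param trial An [eeg_trial()] object (typically already band-pass
#'   filtered, see [fir_bandpass()]).
#' @param N,M Frame length and overlap in samples; defaults 500 and 250.
#' @param bands,pairs Band and pair definitions.
#' @param band_order FIR order for the per-band energy filters.
#' @return Named numeric vector of length 420.
#' @export
eeg_trial_features <- function(trial, N = 500, M = 250, bands = eeg_bands(),
                               pairs = symmetric_pairs(), band_order = 128) {
  stopifnot(inherits(trial, "eeg_trial"))
  fs <- trial$sampling_rate_hz
  nch <- nrow(trial$data)
  abort_if(nch != 30, "expected a 30-channel trial")
  fset <- frame_block(trial, N = N, M = M, apply_window = FALSE)
  w <- hamming_window(N)
  nb <- nrow(bands)

  # Frequency-bin masks shared by all frames.
  half <- N %/% 2L + 1L
  freq <- (seq_len(half) - 1L) * fs / N
  sc <- rep(2, half); sc[1L] <- 1; if (N %% 2L == 0L) sc[half] <- 1
  masks <- lapply(seq_len(nb), function(b) {
    sel <- freq >= bands$low_hz[b] & freq <= bands$high_hz[b]
    abort_if(!any(sel), "band '", bands$name[b],
             "' is narrower than the spectral resolution")
    sel
  })

  aps_acc <- matrix(0, nch, nb)
  for (fr in fset$frames) {
    xw <- t(fr * rep(w, each = nch))          # N x channels
    P <- Mod(stats::mvfft(xw)[seq_len(half), , drop = FALSE])^2 / (fs * N) * sc
    for (b in seq_len(nb)) aps_acc[, b] <- aps_acc[, b] +
      colMeans(P[masks[[b]], , drop = FALSE])
  }
  nfr <- length(fset$frames)
  aps <- aps_acc / nfr

  # Band energies: filter the whole trial once per band, then frame.
  ae <- matrix(0, nch, nb)
  for (b in seq_len(nb)) {
    taps <- fir_band_taps(band_order, bands$low_hz[b], bands$high_hz[b], fs)
    for (ch in seq_len(nch)) {
      y2 <- fir_apply(trial$data[ch, ], taps)^2
      ae[ch, b] <- mean(vapply(fset$starts,
                               function(s) mean(y2[s:(s + N - 1L)]),
                               numeric(1)))
    }
  }

  # DAPS from the averaged APS (linear in APS), using the DAPS band subset.
  db <- daps_bands()
  bidx <- match(db$name, bands$name)
  li <- match(pairs$left, trial$channel_names)
  ri <- match(pairs$right, trial$channel_names)
  abort_if(anyNA(li) || anyNA(ri), "montage lacks required symmetric pairs")
  dvals <- as.vector(t(aps[li, bidx, drop = FALSE] - aps[ri, bidx, drop = FALSE]))
  dnames <- as.vector(t(outer(paste0("DAPS_", pairs$left, "_", pairs$right),
                              db$name, paste, sep = "_")))

  nm_grid <- as.vector(t(outer(trial$channel_names, bands$name, paste,
                               sep = "_")))
  feature_vector(
    c(as.vector(t(aps)), as.vector(t(ae)), dvals),
    c(paste0("APS_", nm_grid), paste0("AE_", nm_grid), dnames),
    modality = "eeg", trial_id = trial$trial_id
  )
}

#' Fit min-max normalization statistics on absolute feature values
#'
#' @param x Numeric matrix, trials x features.
#' @return List with per-column `min` and `max` of `|x|`, class `feature_norm`.
#' @export
feature_norm_fit <- function(x) {
  abort_if(!is.matrix(x) || nrow(x) < 2,
           "need a matrix with at least 2 rows to fit normalization")
  ax <- abs(x)
  structure(list(min = apply(ax, 2L, min), max = apply(ax, 2L, max)),
            class = "feature_norm")
}

#' Apply fitted normalization statistics
#'
#' Maps `(|x| - min) / (max - min)` columnwise; constant columns map to 0.
#'
#' @param x Numeric matrix, trials x features.
#' @param stats A `feature_norm` object from [feature_norm_fit()].
#' @param clip If `TRUE` (default), clip results into \[0, 1\] (needed when
#'   the statistics come from a different subset, e.g. training folds).
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
feature_norm_apply <- function(x, stats, clip = TRUE) {
  stopifnot(inherits(stats, "feature_norm"))
  rng <- stats$max - stats$min
  const <- rng <= 0
  rng[const] <- 1
  y <- sweep(sweep(abs(x), 2L, stats$min, "-"), 2L, rng, "/")
  y[, const] <- 0
  if (clip) y <- pmin(pmax(y, 0), 1)
  y
}

#' Normalize a feature table into \[0, 1\]
#'
#' Per feature (and per participant group when `participants` is supplied),
#' the absolute values are min-max scaled:
#' \eqn{y = (|x| - \min|x|) / (\max|x| - \min|x|)}. Constant features map to
#' 0 with a warning.
#'
#' @param x Numeric matrix, trials x features.
#' @param participants Optional grouping vector (one entry per row); when
#'   given, normalization statistics are computed within each group.
#' @return Matrix of the same shape with all values in \[0, 1\].
#' @export
normalize_features <- function(x, participants = NULL) {
  abort_if(!is.matrix(x) || nrow(x) == 0, "`x` must be a non-empty matrix")
  groups <- if (is.null(participants)) rep(1L, nrow(x)) else participants
  abort_if(length(groups) != nrow(x),
           "`participants` must have one entry per row")
  out <- x
  n_const <- 0L
  for (g in unique(groups)) {
    idx <- which(groups == g)
    abort_if(length(idx) < 2, "need at least 2 rows per group to normalize")
    st <- feature_norm_fit(x[idx, , drop = FALSE])
    n_const <- n_const + sum(st$max - st$min <= 0)
    out[idx, ] <- feature_norm_apply(x[idx, , drop = FALSE], st, clip = FALSE)
  }
  if (n_const > 0)
    warning(n_const, " constant feature column(s) mapped to 0")
  out
}
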