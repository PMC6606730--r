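# Plain-text interchange: CSV conventions for trials, eye data, labels and
# feature tables; JSON serialization of fuzzy measures and filter banks.

#' Write / read an EEG trial as CSV
#'
#' One file per trial: samples in rows, channels in columns, header row of
#' channel names.
#'
#' @param trial An [eeg_trial()].
#' @param path File path.
#' @return `write_eeg_trial_csv` returns `path` invisibly; the reader
#'   returns an [eeg_trial()].
#' @export
write_eeg_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  m <- t(trial$data)
  colnames(m) <- trial$channel_names
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_trial_csv
#' @param sampling_rate_hz Sampling rate of the stored trial.
#' @param trial_id,arousal,valence Metadata to attach.
#' @export
read_eeg_trial_csv <- function(path, sampling_rate_hz,
                               trial_id = basename(path),
                               arousal = NA, valence = NA) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  eeg_trial(t(m), sampling_rate_hz, colnames(m), trial_id = trial_id,
            arousal = arousal, valence = valence)
}

#' Write / read an eye record as CSV
#'
#' Events go to `<stem>_events.csv` (`trial_id,event_type,onset_s,`
#' `duration_s,rotation_deg`), the pupil series to `<stem>_pupil.csv`
#' (`trial_id,time_s,diameter,luminance`).
#'
#' @param record An [eye_record()].
#' @param stem Path stem (without suffix).
#' @return `write_eye_record_csv` returns the two paths invisibly; the
#'   reader returns an [eye_record()].
#' @export
write_eye_record_csv <- function(record, stem) {
  stopifnot(inherits(record, "eye_record"))
  ev <- cbind(trial_id = record$trial_id, record$events)
  pe <- paste0(stem, "_events.csv")
  utils::write.csv(ev, pe, row.names = FALSE)
  np <- length(record$pupil)
  pu <- data.frame(trial_id = record$trial_id,
                   time_s = (seq_len(np) - 1) / record$pupil_rate_hz,
                   diameter = record$pupil,
                   luminance = if (is.null(record$luminance)) NA else
                     record$luminance)
  pp <- paste0(stem, "_pupil.csv")
  utils::write.csv(pu, pp, row.names = FALSE)
  invisible(c(events = pe, pupil = pp))
}

#' @rdname write_eye_record_csv
#' @export
read_eye_record_csv <- function(stem) {
  ev <- utils::read.csv(paste0(stem, "_events.csv"),
                        stringsAsFactors = FALSE)
  pu <- utils::read.csv(paste0(stem, "_pupil.csv"))
  rate <- if (nrow(pu) > 1) 1 / mean(diff(pu$time_s)) else 1
  lum <- if (all(is.na(pu$luminance))) NULL else pu$luminance
  eye_record(ev[, c("event_type", "onset_s", "duration_s", "rotation_deg")],
             pu$diameter, rate, luminance = lum,
             trial_id = as.character(ev$trial_id[1]))
}

#' Write trial labels as CSV
#'
#' Columns `trial_id,arousal_level,valence_level`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param path File path.
#' @export
write_labels_csv <- function(dataset, path) {
  utils::write.csv(data.frame(trial_id = dataset$trial_id,
                              arousal_level = dataset$arousal,
                              valence_level = dataset$valence),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize fuzzy measures to / from JSON
#'
#' Measures are stored as one object per class mapping subset keys (sorted
#' comma-separated classifier indices) to coefficients.
#'
#' @param measures List of [fuzzy_measure()] objects.
#' @param path File path.
#' @export
write_measures_json <- function(measures, path) {
  obj <- lapply(measures, function(m)
    list(n = m$n, coefficients = as.list(m$coefficients)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_measures_json
#' @export
read_measures_json <- function(path) {
  obj <- jsonlite::read_json(path)
  lapply(obj, function(o) {
    keys <- subset_keys(o$n)
    co <- unlist(o$coefficients)[keys]
    fuzzy_measure(o$n, co)
  })
}

#' Serialize a spatial filter bank to / from JSON
#'
#' @param bank A [build_filter_bank()] result.
#' @param path File path.
#' @export
write_filter_bank_json <- function(bank, path) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  obj <- list(n = nrow(bank$mean_filter),
              mean_filter = bank$mean_filter,
              valid_filters = bank$valid_filters,
              validity_flags = bank$validity_flags,
              convergence_flags = bank$convergence_flags)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_filter_bank_json
#' @export
read_filter_bank_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  vf <- obj$valid_filters
  if (is.array(vf) && length(dim(vf)) == 3) {
    vf <- lapply(seq_len(dim(vf)[1]), function(i) vf[i, , ])
  } else if (is.list(vf)) {
    vf <- lapply(vf, function(m) matrix(unlist(m), nrow = obj$n, byrow = TRUE))
  }
  structure(list(valid_filters = vf,
                 mean_filter = matrix(unlist(obj$mean_filter),
                                      nrow = obj$n, byrow = TRUE),
                 validity_flags = as.logical(obj$validity_flags),
                 convergence_flags = as.logical(obj$convergence_flags)),
            class = "spatial_filter_bank")
}

#' Write a feature table as CSV
#'
#' Header = feature names plus `trial_id` and the labels.
#'
#' @param x Feature matrix (trials x features).
#' @param trial_id,arousal,valence Per-trial metadata.
#' @param path File path.
#' @export
write_feature_csv <- function(x, trial_id, arousal, valence, path) {
  df <- data.frame(trial_id = trial_id, arousal_level = arousal,
                   valence_level = valence, x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
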