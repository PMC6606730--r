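# Shared fixtures, computed lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# A small configuration for fast unit tests (8-s trials).
small_cfg <- function(npl = 2, dur = 8, seed = 11)
  sim_config(n_trials_per_level = npl, trial_duration_s = dur, seed = seed)

# A single filtered small trial plus its frames.
small_trial <- function() fixture("small_trial", {
  fir_bandpass(simulate_eeg_trial(small_cfg(), 3, 3, seed = 21))
})

# Random monotone fuzzy measure (via upward repair of uniform draws).
random_measure <- function(n) {
  k <- 2^n - 2
  emofuse:::unstack_measures(stats::runif(k), n, 1)[[1]]
}

# Brute-force Choquet oracle via the layer-cake (threshold) representation:
# integral of mu({ f >= t }) dt, evaluated over the sorted unique values.
# Independent of the sorting-based implementation.
choquet_oracle <- function(f, mu) {
  th <- sort(unique(f))
  prev <- 0
  total <- 0
  for (t in th) {
    lev <- which(f >= t)
    total <- total + (t - prev) * measure_value(mu, lev)
    prev <- t
  }
  total
}

# Area under the ROC curve for scores of two groups (rank statistic).
auc_score <- function(pos, neg) {
  r <- rank(c(pos, neg))[seq_along(pos)]
  (sum(r) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Mid-size labeled dataset with extracted features: 40 trials/level of 20-s
# trials (200 trials), reused by the recoverability and evaluation tests.
feature_dataset_200 <- function() fixture("feature_dataset_200", {
  cfg <- sim_config(n_trials_per_level = 40, trial_duration_s = 20,
                    seed = 2024)
  extract_dataset_features(simulate_dataset(cfg))
})
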