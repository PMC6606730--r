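# Evaluation: accuracy and confusion matrices, and repeated stratified
# cross-validation of the fused multimodal model.

#' Accuracy and row-normalized confusion matrix
#'
#' @param predicted,truth Vectors of intensity levels of equal, nonzero
#'   length.
#' @param levels Class levels; default 1-5.
#' @return List with `accuracy` (fraction of exact matches) and `confusion`
#'   (matrix with `confusion[i, j] = P(predicted j | truth i)`; rows with no
#'   truth instances are zero).
#' @export
evaluate_predictions <- function(predicted, truth, levels = 1:5) {
  abort_if(length(predicted) != length(truth),
           "`predicted` and `truth` must have equal length")
  abort_if(length(truth) == 0, "empty input")
  p <- factor(as.character(predicted), levels = as.character(levels))
  t <- factor(as.character(truth), levels = as.character(levels))
  counts <- table(t, p)
  rs <- rowSums(counts)
  conf <- counts / ifelse(rs > 0, rs, 1)
  conf <- matrix(conf, nrow = length(levels),
                 dimnames = list(truth = levels, predicted = levels))
  list(accuracy = mean(as.character(p) == as.character(t)), confusion = conf)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds (fold offsets rotated per class so fold sizes stay
# balanced).
stratified_folds <- function(labels, folds) {
  y <- factor(labels)
  abort_if(any(table(y) < folds),
           "every class needs at least `folds` samples for stratified folds")
  fold <- integer(length(y))
  off <- 0L
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- ((seq_along(idx) - 1L + off) %% folds) + 1L
    off <- off + length(idx) %% folds
  }
  fold
}

#' Repeated stratified cross-validation of the fused model
#'
#' Runs `repeats` x `folds` cross-validation: for each split, feature
#' normalization statistics, per-modality SVMs and fuzzy measures are fitted
#' on the training folds only; the held-out fold is normalized with the
#' training statistics (clipped to \[0, 1\]) and evaluated. Reports the mean
#' accuracy per modality and for the fusion, plus row-normalized confusion
#' matrices averaged over splits.
#'
#' @param features Named list of unnormalized modality feature matrices
#'   (e.g. from [extract_dataset_features()]).
#' @param labels Intensity levels (1-5), one per trial.
#' @param repeats,folds Cross-validation design; default 10 x 5.
#' @param seed Seed for the fold shuffling; the report is deterministic
#'   given the seed.
#' @param cost,gamma SVM parameters.
#' @param measures `"qp"` or `"uniform"` fusion measures.
#' @param normalize `"train_fold"` (default; statistics from training folds
#'   only, leak-free) or `"global"` (statistics from the full table before
#'   splitting).
#' @return Object of class `emofuse_cv`: list with `accuracy` (data frame:
#'   model, mean, sd over splits), `confusion` (list of averaged matrices
#'   per model), `repeats`, `folds`, `seed`.
#' @export
cross_validate <- function(features, labels, repeats = 10, folds = 5,
                           seed = 1, cost = 1, gamma = NULL,
                           measures = c("qp", "uniform"),
                           normalize = c("train_fold", "global")) {
  measures <- match.arg(measures)
  normalize <- match.arg(normalize)
  y <- factor(labels)
  mods <- names(features)
  models <- c(mods, "fused")
  lv <- levels(y)
  nl <- length(lv)
  if (normalize == "global")
    features <- lapply(features, normalize_features)
  acc <- matrix(NA_real_, repeats * folds, length(models),
                dimnames = list(NULL, models))
  conf <- lapply(models, function(m) matrix(0, nl, nl,
                                            dimnames = list(truth = lv,
                                                            predicted = lv)))
  names(conf) <- models
  split_i <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, folds)
      for (f in seq_len(folds)) {
        split_i <- split_i + 1L
        tr <- fold != f
        te <- !tr
        if (normalize == "train_fold") {
          stats_tr <- lapply(features, function(x)
            feature_norm_fit(x[tr, , drop = FALSE]))
          xtr <- mapply(function(x, st)
            feature_norm_apply(x[tr, , drop = FALSE], st),
            features, stats_tr, SIMPLIFY = FALSE)
          xte <- mapply(function(x, st)
            feature_norm_apply(x[te, , drop = FALSE], st),
            features, stats_tr, SIMPLIFY = FALSE)
        } else {
          xtr <- lapply(features, function(x) x[tr, , drop = FALSE])
          xte <- lapply(features, function(x) x[te, , drop = FALSE])
        }
        fit <- emofuse(xtr, y[tr], cost = cost, gamma = gamma,
                       measures = measures)
        for (m in mods) {
          pm <- predict(fit$classifiers[[m]], xte[[m]])
          ev <- evaluate_predictions(pm, y[te], levels = lv)
          acc[split_i, m] <- ev$accuracy
          conf[[m]] <- conf[[m]] + ev$confusion
        }
        pf <- predict(fit, xte)
        ev <- evaluate_predictions(pf, y[te], levels = lv)
        acc[split_i, "fused"] <- ev$accuracy
        conf[["fused"]] <- conf[["fused"]] + ev$confusion
      }
    }
  })
  nsplit <- repeats * folds
  conf <- lapply(conf, function(cm) {
    cm <- cm / nsplit
    sw <- rowSums(cm)
    cm / ifelse(sw > 0, sw, 1)  # renormalize rows exactly
  })
  structure(
    list(accuracy = data.frame(model = models,
                               mean = colMeans(acc),
                               sd = apply(acc, 2L, stats::sd),
                               row.names = NULL),
         confusion = conf, repeats = repeats, folds = folds, seed = seed,
         measures = measures, normalize = normalize),
    class = "emofuse_cv"
  )
}

#' @export
print.emofuse_cv <- function(x, digits = 3, ...) {
  cat(x$repeats, "x", x$folds, "cross-validation (",
    if (x$measures == "qp") "QP-learned" else "uniform", "fusion measures )\n")
  df <- x$accuracy
  df$mean <- round(df$mean, digits)
  df$sd <- round(df$sd, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cross-validate both emotion dimensions
#'
#' Convenience wrapper: runs [cross_validate()] on the arousal and valence
#' labels of an extracted dataset and returns both reports.
#'
#' @param extracted An [extract_dataset_features()] result.
#' @param ... Passed to [cross_validate()].
#' @return Named list with elements `arousal` and `valence`, each an
#'   `emofuse_cv` report.
#' @export
cross_validate_dual <- function(extracted, ...) {
  list(
    arousal = cross_validate(extracted$features, extracted$arousal, ...),
    valence = cross_validate(extracted$features, extracted$valence, ...)
  )
}
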