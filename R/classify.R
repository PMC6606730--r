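# Per-modality SVM classifiers with deterministic confidence factors, and
# the fused dual-modality estimator.

#' Train a per-modality multiclass SVM
#'
#' RBF-kernel support vector machine (penalty factor `cost = 1` by default)
#' over normalized features in \[0, 1\]. Confidence factors are derived
#' deterministically from the pairwise decision values: each pairwise margin
#' is mapped through a logistic function and the pairwise estimates are
#' coupled into a per-class probability vector (rows sum to 1).
#'
#' @param x Numeric matrix, samples x features, values in \[0, 1\].
#' @param y Class labels (factor or integer levels); at least two classes.
#' @param cost SVM penalty factor; default 1.
#' @param gamma RBF kernel width; default the variance-adaptive
#'   `1 / (ncol(x) * mean feature variance)`, which keeps the kernel
#'   informative when many normalized features have small variance.
#' @return Object of class `modality_classifier`.
#' @export
train_modality_classifier <- function(x, y, cost = 1, gamma = NULL) {
  abort_if(!is.matrix(x), "`x` must be a matrix")
  y <- factor(y)
  abort_if(nlevels(y) < 2, "training set contains a single class")
  abort_if(nrow(x) != length(y), "one label per row of `x` is required")
  if (is.null(gamma)) {
    v <- mean(apply(x, 2L, stats::var))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
  }
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, levels = levels(y), gamma = gamma, cost = cost),
            class = "modality_classifier")
}

#' @export
print.modality_classifier <- function(x, ...) {
  cat("Modality classifier: RBF SVM, cost", x$cost, ", gamma",
      format(x$gamma, digits = 3), ",", length(x$levels), "classes\n")
  invisible(x)
}

# Wu-Lin pairwise coupling: combine pairwise win probabilities r[i, j]
# (= P(class i | i or j)) into a probability vector. Solved exactly via the
# KKT linear system of the quadratic coupling objective; deterministic.
couple_pairwise <- function(r) {
  k <- nrow(r)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        Q[i, i] <- sum(r[-i, i]^2)
      } else {
        Q[i, j] <- -r[j, i] * r[i, j]
      }
    }
  }
  M <- rbind(cbind(Q, 1), c(rep(1, k), 0))
  p <- tryCatch(solve(M, c(rep(0, k), 1))[seq_len(k)],
                error = function(e) rep(1 / k, k))
  p <- pmin(pmax(p, 0), 1)
  s <- sum(p)
  if (s <= 0) rep(1 / k, k) else p / s
}

#' Per-class confidence factors for new samples
#'
#' @param object A [train_modality_classifier()] fit.
#' @param newdata Numeric matrix, samples x features.
#' @return Matrix samples x classes of confidences in \[0, 1\], rows
#'   summing to 1, columns ordered by class level.
#' @export
predict_confidence <- function(object, newdata) {
  stopifnot(inherits(object, "modality_classifier"))
  pred <- stats::predict(object$fit, newdata, decision.values = TRUE)
  dec <- attr(pred, "decision.values")
  lev <- object$levels
  k <- length(lev)
  pairs <- strsplit(colnames(dec), "/")
  out <- matrix(0, nrow(newdata), k, dimnames = list(NULL, lev))
  for (s in seq_len(nrow(newdata))) {
    r <- matrix(0.5, k, k)
    for (p in seq_along(pairs)) {
      i <- match(pairs[[p]][1], lev)
      j <- match(pairs[[p]][2], lev)
      pij <- 1 / (1 + exp(-dec[s, p]))
      r[i, j] <- pij
      r[j, i] <- 1 - pij
    }
    out[s, ] <- couple_pairwise(r)
  }
  out
}

#' Predicted classes from a modality classifier
#'
#' @inheritParams predict_confidence
#' @param type `"class"` (default) or `"confidence"`.
#' @return Class labels, or the confidence matrix.
#' @export
predict.modality_classifier <- function(object, newdata,
                                        type = c("class", "confidence"), ...) {
  type <- match.arg(type)
  if (type == "confidence") return(predict_confidence(object, newdata))
  conf <- predict_confidence(object, newdata)
  factor(object$levels[max.col(conf, ties.method = "first")],
         levels = object$levels)
}

#' Fit the fused multimodal emotion-intensity model
#'
#' Trains one RBF-SVM per modality on normalized features, derives
#' per-sample confidence profiles, and learns one fuzzy measure per class by
#' quadratic programming so that the discrete Choquet integral of the
#' per-modality confidences maximizes the margin between the true class and
#' its strongest competitor. Prediction fuses the modality classifiers
#' through the learned measures.
#'
#' @param features Named list of numeric matrices (one per modality, e.g.
#'   `list(eeg = ..., eye = ...)`), equal row counts, values in \[0, 1\]
#'   (see [normalize_features()]).
#' @param labels Class labels (intensity levels 1-5), one per row.
#' @param cost,gamma SVM parameters, see [train_modality_classifier()].
#' @param measures `"qp"` (default) to learn fuzzy measures, or `"uniform"`
#'   for mean fusion.
#' @param profile_folds Internal stratified folds used to obtain
#'   out-of-fold confidence profiles for measure learning (default 5).
#'   In-sample confidences overstate a weak modality's reliability, so the
#'   fuzzy measures are learned on held-out confidences, as in stacked
#'   generalization; set to 1 to learn on in-sample profiles.
#' @param profile_seed Seed for the internal fold shuffling.
#' @return Object of class `emofuse` with components `classifiers`,
#'   `measures`, `levels`, `modalities`.
#' @seealso [predict.emofuse()], [cross_validate()]
#' @export
emofuse <- function(features, labels, cost = 1, gamma = NULL,
                    measures = c("qp", "uniform"), profile_folds = 5,
                    profile_seed = 1) {
  measures <- match.arg(measures)
  abort_if(!is.list(features) || is.null(names(features)) ||
             any(names(features) == ""),
           "`features` must be a named list of modality matrices")
  ns <- vapply(features, nrow, integer(1))
  abort_if(length(unique(ns)) != 1,
           "all modality matrices must have the same number of rows")
  y <- factor(labels)
  abort_if(length(y) != ns[1], "one label per sample is required")
  classifiers <- lapply(features, train_modality_classifier, y = y,
                        cost = cost, gamma = gamma)
  m <- nlevels(y)
  n <- length(features)
  mu <- if (measures == "qp" && n >= 2) {
    conf <- oof_confidences(features, y, cost, gamma, profile_folds,
                            profile_seed)
    profiles <- lapply(seq_len(ns[1]), function(s)
      do.call(rbind, lapply(conf, function(cm) cm[s, ])))
    learn_fuzzy_measures(profiles, as.integer(y), m, n)
  } else {
    replicate(m, uniform_measure(max(n, 2)), simplify = FALSE)
  }
  structure(
    list(classifiers = classifiers, measures = mu, levels = levels(y),
         modalities = names(features), n_train = ns[1],
         measure_mode = measures, call = match.call()),
    class = "emofuse"
  )
}

# Out-of-fold confidence matrices per modality: each training sample's
# confidence profile comes from classifiers that did not see it, so the
# fuzzy measures reflect out-of-sample reliability. Falls back to in-sample
# confidences when classes are too small to fold.
oof_confidences <- function(features, y, cost, gamma, folds, seed) {
  folds <- min(folds, min(table(y)))
  insample <- function() lapply(features, function(xm)
    predict_confidence(train_modality_classifier(xm, y, cost, gamma), xm))
  if (folds < 2) return(insample())
  fold <- with_seed(seed, stratified_folds(y, folds))
  out <- lapply(features, function(xm)
    matrix(NA_real_, nrow(xm), nlevels(y),
           dimnames = list(NULL, levels(y))))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < nlevels(y)) return(insample())
    for (mod in names(features)) {
      cl <- train_modality_classifier(features[[mod]][tr, , drop = FALSE],
                                      y[tr], cost, gamma)
      out[[mod]][!tr, ] <-
        predict_confidence(cl, features[[mod]][!tr, , drop = FALSE])
    }
  }
  out
}

#' Predict from a fused multimodal model
#'
#' @param object An [emofuse()] fit.
#' @param newdata Named list of modality matrices matching the fit.
#' @param type `"class"` (default), `"confidence"` (global per-class fused
#'   confidences) or `"profile"` (list of per-sample classifier x class
#'   profiles).
#' @param ... Unused.
#' @return Factor of predicted levels, a samples x classes matrix, or a
#'   list of profiles.
#' @export
predict.emofuse <- function(object, newdata,
                            type = c("class", "confidence", "profile"), ...) {
  type <- match.arg(type)
  abort_if(!all(object$modalities %in% names(newdata)),
           "`newdata` must contain matrices for: ",
           paste(object$modalities, collapse = ", "))
  conf <- mapply(function(cl, mod) predict_confidence(cl, newdata[[mod]]),
                 object$classifiers, object$modalities, SIMPLIFY = FALSE)
  ns <- nrow(conf[[1]])
  profiles <- lapply(seq_len(ns), function(s)
    do.call(rbind, lapply(conf, function(cm) cm[s, ])))
  if (type == "profile") return(profiles)
  g <- t(vapply(profiles, global_confidence, numeric(length(object$levels)),
                measures = object$measures))
  colnames(g) <- object$levels
  if (type == "confidence") return(g)
  factor(object$levels[apply(g, 1L, which.max)], levels = object$levels)
}

#' @export
print.emofuse <- function(x, ...) {
  cat("Fused multimodal emotion-intensity model\n")
  cat("  modalities :", paste(x$modalities, collapse = ", "), "\n")
  cat("  classes    :", paste(x$levels, collapse = ", "), "\n")
  cat("  training n :", x$n_train, "\n")
  cat("  fusion     :",
      if (x$measure_mode == "qp") "Choquet integral, QP-learned fuzzy measures"
      else "Choquet integral, uniform (mean) measure", "\n")
  invisible(x)
}

#' @export
summary.emofuse <- function(object, ...) {
  imp <- coef(object)
  cat("Fused multimodal emotion-intensity model\n\n")
  cat("Singleton measure coefficients (classifier importance per class):\n")
  sing <- imp[, seq_along(object$modalities), drop = FALSE]
  colnames(sing) <- object$modalities
  print(round(sing, 3))
  invisible(list(importance = sing, coefficients = imp))
}

#' Fuzzy-measure coefficients of a fitted model
#'
#' @param object An [emofuse()] fit.
#' @param ... Unused.
#' @return Matrix classes x subsets of measure coefficients (subset keys as
#'   column names).
#' @export
coef.emofuse <- function(object, ...) {
  co <- t(vapply(object$measures, function(m) m$coefficients,
                 object$measures[[1]]$coefficients))
  rownames(co) <- object$levels
  co
}
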