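# Decision-level fusion: fuzzy measures on classifier subsets, the discrete
# Choquet integral, quadratic-programming measure learning, and fused
# classification.

#' Enumerate nonempty proper subsets of 1..n
#'
#' Subset keys in the canonical coefficient ordering: singletons first, then
#' pairs, and so on, each size in lexicographic order. A key is the
#' comma-separated sorted index set, e.g. `"1,3"`.
#'
#' @param n Number of classifiers.
#' @return Character vector of length `2^n - 2`.
#' @export
subset_keys <- function(n) {
  abort_if(!is_count(n) || n < 2, "`n` must be an integer >= 2")
  unlist(lapply(seq_len(n - 1L), function(sz)
    apply(utils::combn(n, sz), 2L, paste, collapse = ",")))
}

subset_key <- function(idx) paste(sort(idx), collapse = ",")

#' Construct a fuzzy measure on classifier subsets
#'
#' A fuzzy measure is a set function on subsets of the classifier index set
#' with mu(empty) = 0, mu(full set) = 1, and monotone under inclusion. Only
#' the coefficients of nonempty proper subsets are stored (the boundary
#' values are implicit).
#'
#' @param n Number of classifiers.
#' @param coefficients Numeric vector of length `2^n - 2` in \[0, 1\], named
#'   by [subset_keys()] order (names optional; the canonical order is
#'   assumed).
#' @param check If `TRUE` (default), validate range and monotonicity.
#' @return Object of class `fuzzy_measure`.
#' @export
fuzzy_measure <- function(n, coefficients, check = TRUE) {
  keys <- subset_keys(n)
  abort_if(length(coefficients) != length(keys),
           "expected ", length(keys), " coefficients for n = ", n,
           ", got ", length(coefficients))
  co <- as.numeric(coefficients)
  names(co) <- keys
  m <- structure(list(n = as.integer(n), coefficients = co),
                 class = "fuzzy_measure")
  if (check) validate_measure(m)
  m
}

validate_measure <- function(m, tol = 1e-8) {
  co <- m$coefficients
  abort_if(any(co < -tol | co > 1 + tol),
           "fuzzy measure coefficients must lie in [0, 1]")
  cov <- cover_pairs(m$n)
  for (k in seq_len(nrow(cov))) {
    a <- if (cov$from[k] == "") 0 else co[[cov$from[k]]]
    b <- if (cov$to[k] == "full") 1 else co[[cov$to[k]]]
    abort_if(a > b + tol, "fuzzy measure is not monotone: mu({",
             cov$from[k], "}) > mu({", cov$to[k], "})")
  }
  invisible(m)
}

# All cover relations of the subset lattice restricted to proper subsets,
# plus the boundary covers from the empty set and to the full set.
cover_pairs <- function(n) {
  keys <- subset_keys(n)
  sets <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1]]))
  from <- character(0)
  to <- character(0)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    for (e in setdiff(seq_len(n), s)) {
      sup <- sort(c(s, e))
      from <- c(from, keys[i])
      to <- c(to, if (length(sup) == n) "full" else subset_key(sup))
    }
    if (length(s) == 1L) {
      from <- c(from, "")
      to <- c(to, keys[i])
    }
  }
  unique(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

#' Evaluate a fuzzy measure on an index set
#'
#' @param m A [fuzzy_measure()].
#' @param idx Integer vector of classifier indices (possibly empty).
#' @return mu(idx): 0 for the empty set, 1 for the full set, the stored
#'   coefficient otherwise.
#' @export
measure_value <- function(m, idx) {
  stopifnot(inherits(m, "fuzzy_measure"))
  idx <- unique(idx)
  if (length(idx) == 0) return(0)
  if (length(idx) == m$n) return(1)
  m$coefficients[[subset_key(idx)]]
}

#' Uniform (additive, symmetric) fuzzy measure
#'
#' mu(S) = |S| / n: the Choquet integral with respect to this measure is the
#' arithmetic mean. Used as initialization and as the fallback when measure
#' learning fails.
#'
#' @param n Number of classifiers.
#' @return A [fuzzy_measure()].
#' @export
uniform_measure <- function(n) {
  keys <- subset_keys(n)
  sizes <- lengths(strsplit(keys, ","))
  fuzzy_measure(n, sizes / n)
}

#' @export
print.fuzzy_measure <- function(x, digits = 3, ...) {
  cat("Fuzzy measure on", x$n, "classifiers\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Discrete Choquet integral
#'
#' Aggregates confidence factors `f` (one per classifier, each in \[0, 1\])
#' with respect to a fuzzy measure: with `f` sorted ascending and
#' `f(x_(0)) = 0`,
#' \deqn{\zeta_\mu(f) = \sum_i [f(x_{(i)}) - f(x_{(i-1)})]\,\mu(A_{(i)})}
#' where \eqn{A_{(i)}} is the set of the `n - i + 1` largest-valued
#' classifier indices. Generalizes the weighted mean (additive measures),
#' the minimum and the maximum.
#'
#' @param f Numeric vector of length `n`, values in \[0, 1\].
#' @param mu A [fuzzy_measure()] with matching `n`.
#' @return Scalar in `[min(f), max(f)]`.
#' @export
choquet_integral <- function(f, mu) {
  stopifnot(inherits(mu, "fuzzy_measure"))
  abort_if(length(f) != mu$n, "length(f) must equal the measure's n")
  abort_if(any(!is.finite(f)) || any(f < -1e-9 | f > 1 + 1e-9),
           "confidence factors must lie in [0, 1]")
  f <- pmin(pmax(f, 0), 1)
  ord <- order(f)
  fs <- f[ord]
  prev <- 0
  total <- 0
  for (i in seq_along(fs)) {
    total <- total + (fs[i] - prev) * measure_value(mu, ord[i:length(fs)])
    prev <- fs[i]
  }
  total
}

# Linear representation of the Choquet integral in the measure coefficients:
# zeta_mu(f) = min(f) + sum_k coef[k] * mu(subset_k) over proper subsets.
choquet_coeffs <- function(f, keys) {
  n <- length(f)
  ord <- order(f)
  fs <- f[ord]
  coef <- stats::setNames(numeric(length(keys)), keys)
  for (i in 2:n) {
    coef[[subset_key(ord[i:n])]] <- fs[i] - fs[i - 1L]
  }
  list(const = fs[1L], coef = coef)
}

#' Global per-class confidence by Choquet fusion
#'
#' For each class j, fuses the per-classifier confidence factors for that
#' class (column j of the profile) with the class's own fuzzy measure.
#'
#' @param profile Numeric matrix, classifiers x classes, values in \[0, 1\].
#' @param measures List of [fuzzy_measure()] objects, one per class.
#' @return Numeric vector of length `ncol(profile)` of global confidences.
#' @export
global_confidence <- function(profile, measures) {
  abort_if(!is.matrix(profile), "`profile` must be a classifiers x classes matrix")
  abort_if(length(measures) != ncol(profile),
           "need one fuzzy measure per class (", ncol(profile), "), got ",
           length(measures))
  vapply(seq_len(ncol(profile)), function(j)
    choquet_integral(profile[, j], measures[[j]]), numeric(1))
}

#' Classify a sample from its fused confidence profile
#'
#' Returns the class with the highest [global_confidence()]; ties resolve to
#' the lowest class id with a message.
#'
#' @inheritParams global_confidence
#' @param class_ids Class identifiers; default `1:ncol(profile)`.
#' @return A single class id.
#' @export
classify_fused <- function(profile, measures,
                           class_ids = seq_len(ncol(profile))) {
  g <- global_confidence(profile, measures)
  top <- which(g == max(g))
  if (length(top) > 1L)
    message("fused confidence tie; choosing the lowest class id")
  class_ids[top[1L]]
}

#' Build the quadratic program for fuzzy-measure learning
#'
#' Expands the squared-margin training objective into an explicit quadratic
#' form over the stacked measure-coefficient vector (one block of
#' `2^n - 2` coefficients per class, in [subset_keys()] order). For each
#' training profile with true class t, the margin deficit
#' `(Phi_mu^t(C_t) - Phi_mu^c(C_c) - 1)^2` is accumulated, where the
#' competing class c is the strongest competitor under mean fusion (fixed,
#' so the objective stays quadratic). Constraints encode the \[0, 1\]
#' bounds and all monotonicity cover relations of the subset lattice.
#'
#' @param profiles List of classifiers x classes confidence matrices.
#' @param labels Integer vector of true classes (1..m), one per profile.
#' @param n_classes Number of classes m.
#' @param n_classifiers Number of classifiers n.
#' @return List of class `measure_qp` with `D` (quadratic matrix), `d`
#'   (linear term), `constant`, `A`, `b` (inequalities `A mu <= b`), `lb`,
#'   `ub`, `keys`, `n`, `m`. The number of variables is `m * (2^n - 2)`.
#' @export
build_measure_qp <- function(profiles, labels, n_classes, n_classifiers) {
  m <- n_classes
  n <- n_classifiers
  abort_if(length(profiles) != length(labels),
           "one label per training profile is required")
  abort_if(!all(sort(unique(labels)) %in% seq_len(m)),
           "labels must lie in 1..n_classes")
  abort_if(!all(seq_len(m) %in% labels),
           "every class must be represented in the training profiles")
  keys <- subset_keys(n)
  K <- length(keys)
  nv <- m * K
  D <- matrix(0, nv, nv)
  dlin <- numeric(nv)
  const <- 0
  for (s in seq_along(profiles)) {
    P <- profiles[[s]]
    abort_if(nrow(P) != n || ncol(P) != m,
             "profile ", s, " is not ", n, " x ", m)
    t <- labels[s]
    comp <- setdiff(seq_len(m), t)
    c_star <- comp[which.max(colMeans(P)[comp])]
    ct <- choquet_coeffs(P[, t], keys)
    cc <- choquet_coeffs(P[, c_star], keys)
    g <- numeric(nv)
    g[(t - 1L) * K + seq_len(K)] <- ct$coef
    g[(c_star - 1L) * K + seq_len(K)] <-
      g[(c_star - 1L) * K + seq_len(K)] - cc$coef
    dk <- ct$const - cc$const - 1
    D <- D + 2 * tcrossprod(g)
    dlin <- dlin + 2 * dk * g
    const <- const + dk^2
  }
  # Monotonicity: mu(S) - mu(S + e) <= 0 over proper-subset cover pairs,
  # replicated per class block. Boundary covers become the box constraints.
  cov <- cover_pairs(n)
  inner <- cov[cov$from != "" & cov$to != "full", , drop = FALSE]
  rows <- list()
  for (j in seq_len(m)) {
    off <- (j - 1L) * K
    for (k in seq_len(nrow(inner))) {
      r <- numeric(nv)
      r[off + match(inner$from[k], keys)] <- 1
      r[off + match(inner$to[k], keys)] <- -1
      rows[[length(rows) + 1L]] <- r
    }
  }
  A <- if (length(rows)) do.call(rbind, rows) else NULL
  b <- if (length(rows)) numeric(length(rows)) else NULL
  structure(
    list(D = D, d = dlin, constant = const, A = A, b = b,
         lb = numeric(nv), ub = rep(1, nv), keys = keys,
         n = n, m = m),
    class = "measure_qp"
  )
}

#' Evaluate the quadratic training objective at a stacked measure vector
#'
#' @param qp A [build_measure_qp()] result.
#' @param mu Numeric vector of length `m * (2^n - 2)`.
#' @return The objective value `0.5 mu' D mu + d' mu + constant`, which
#'   equals the direct squared-margin training error.
#' @export
qp_objective <- function(qp, mu) {
  stopifnot(inherits(qp, "measure_qp"))
  abort_if(length(mu) != length(qp$d), "wrong measure vector length")
  as.numeric(0.5 * t(mu) %*% qp$D %*% mu + sum(qp$d * mu) + qp$constant)
}

# Direct (non-expanded) evaluation of the squared-margin objective, used as
# an independent check of the quadratic expansion.
measure_training_error <- function(profiles, labels, measures) {
  m <- length(measures)
  total <- 0
  for (s in seq_along(profiles)) {
    P <- profiles[[s]]
    t <- labels[s]
    comp <- setdiff(seq_len(m), t)
    c_star <- comp[which.max(colMeans(P)[comp])]
    phi_t <- choquet_integral(P[, t], measures[[t]])
    phi_c <- choquet_integral(P[, c_star], measures[[c_star]])
    total <- total + (phi_t - phi_c - 1)^2
  }
  total
}

# Stack a list of per-class measures into the QP variable vector.
stack_measures <- function(measures) {
  unlist(lapply(measures, function(m) unname(m$coefficients)))
}

unstack_measures <- function(mu, n, m, repair = TRUE) {
  K <- 2^n - 2
  lapply(seq_len(m), function(j) {
    co <- pmin(pmax(mu[(j - 1L) * K + seq_len(K)], 0), 1)
    if (repair) {
      # Enforce monotonicity along the lattice by upward propagation of tiny
      # numerical violations.
      keys <- subset_keys(n)
      sets <- lapply(keys, function(k) as.integer(strsplit(k, ",")[[1]]))
      ord <- order(lengths(sets))
      for (i in ord) {
        s <- sets[[i]]
        if (length(s) == 1L) next
        subs <- utils::combn(s, length(s) - 1L)
        for (cidx in seq_len(ncol(subs))) {
          k2 <- subset_key(subs[, cidx])
          co[i] <- max(co[i], co[[match(k2, keys)]])
        }
      }
      co <- pmin(co, 1)
    }
    fuzzy_measure(n, co)
  })
}

#' Learn per-class fuzzy measures by quadratic programming
#'
#' Solves the convex quadratic program built by [build_measure_qp()]
#' (squared-margin objective, \[0, 1\] boxes, monotonicity constraints) and
#' returns one fuzzy measure per class. A small ridge keeps the quadratic
#' matrix positive definite. If the solver fails, or the solution does not
#' improve on the uniform measure, the uniform (additive) measure is
#' returned for every class with a warning.
#'
#' @inheritParams build_measure_qp
#' @param ridge Relative ridge added to the quadratic matrix diagonal.
#' @return List of `n_classes` [fuzzy_measure()] objects with attribute
#'   `objective` (achieved training error).
#' @export
learn_fuzzy_measures <- function(profiles, labels, n_classes, n_classifiers,
                                 ridge = 1e-7) {
  qp <- build_measure_qp(profiles, labels, n_classes, n_classifiers)
  unif <- replicate(n_classes, uniform_measure(n_classifiers),
                    simplify = FALSE)
  j_unif <- qp_objective(qp, stack_measures(unif))
  scale <- max(diag(qp$D), 1)
  C <- qp$D + diag(ridge * scale, nrow(qp$D))
  sol <- tryCatch(
    pracma::quadprog(C, qp$d, A = qp$A, b = qp$b, lb = qp$lb, ub = qp$ub),
    error = function(e) NULL
  )
  if (is.null(sol) || !is.numeric(sol$xmin) || any(!is.finite(sol$xmin))) {
    warning("fuzzy-measure QP solver failed; falling back to the uniform measure")
    attr(unif, "objective") <- j_unif
    return(unif)
  }
  measures <- unstack_measures(sol$xmin, n_classifiers, n_classes)
  j_learned <- qp_objective(qp, stack_measures(measures))
  if (j_learned > j_unif + 1e-9) {
    warning("learned measures did not improve on the uniform measure; ",
            "using the uniform measure")
    attr(unif, "objective") <- j_unif
    return(unif)
  }
  attr(measures, "objective") <- j_learned
  measures
}
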