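# Spatial features: Infomax ICA filter bank with validity judgment and
# SVD-based spatial features of the mean-filter projection.

#' Fit Infomax ICA to one trial
#'
#' Blind source separation by information maximization with the natural
#' gradient and a logistic nonlinearity, after PCA whitening. Suitable for
#' the super-Gaussian sources typical of EEG. The returned unmixing matrix
#' `W` includes the whitening transform, so `W %*% x` are the independent
#' components, and `A = solve(W)` is the mixing matrix (component scalp
#' maps in its columns).
#'
#' @param x Numeric matrix, channels x samples; needs at least 10 samples
#'   per channel.
#' @param max_iter Maximum number of full-batch natural-gradient iterations
#'   (default 2000).
#' @param tol Convergence tolerance on the mean squared natural-gradient
#'   norm (default 1e-9).
#' @param seed Integer seed for the random orthogonal initialization of the
#'   unmixing matrix; the fit is deterministic given the seed.
#' @param lrate Initial learning rate (default 0.1), annealed when the
#'   gradient norm grows.
#' @return List of class `ica_fit` with elements `W`, `A`, `converged`,
#'   `iterations`. Non-convergence is flagged, not an error.
#' @export
fit_ica <- function(x, max_iter = 2000, tol = 1e-9, seed = 1, lrate = 0.1) {
  abort_if(!is.matrix(x) || !is.numeric(x), "`x` must be a numeric matrix")
  abort_if(any(!is.finite(x)), "`x` contains non-finite values")
  n <- nrow(x)
  s <- ncol(x)
  abort_if(s < 10 * n, "need at least 10 samples per channel (",
           s, " samples for ", n, " channels)")
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc) / s
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, max(eg$values) * 1e-12)
  wh <- diag(1 / sqrt(ev), n) %*% t(eg$vectors)  # whitening matrix
  xw <- wh %*% xc

  # Random orthogonal initialization, seeded.
  W <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(n * n), n))))
  lr <- lrate
  Iden <- diag(n)
  converged <- FALSE
  last_change <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- W %*% xw
    y <- 1 / (1 + exp(-u))
    G <- Iden + ((1 - 2 * y) %*% t(u)) / s
    Wnew <- W + lr * G %*% W
    if (any(!is.finite(Wnew))) {  # blow-up: retry colder
      lr <- lr * 0.5
      next
    }
    W <- Wnew
    change <- sum(G^2) / n^2
    if (change > last_change * 1.2) lr <- lr * 0.8
    last_change <- change
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  Wfull <- W %*% wh
  A <- tryCatch(solve(Wfull), error = function(e) MASS_ginv(Wfull))
  structure(list(W = Wfull, A = A, converged = converged, iterations = it),
            class = "ica_fit")
}

# Moore-Penrose fallback for a numerically singular unmixing matrix.
MASS_ginv <- function(m) {
  sv <- svd(m)
  pos <- sv$d > max(sv$d) * 1e-10
  sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
}

#' @export
print.ica_fit <- function(x, ...) {
  cat("Infomax ICA fit:", nrow(x$W), "components,",
      if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "passes\n")
  invisible(x)
}

#' Validity judgment of an ICA spatial filter
#'
#' For each column of the absolute mixing matrix `|A|` (one component scalp
#' map), the row index of its maximum is recorded in an index vector `D`.
#' The filter is valid iff `D` contains every channel index exactly once
#' (i.e. is a permutation): every component projects maximally onto a
#' distinct channel. Ties within a column resolve to the lowest row index
#' with a message.
#'
#' @param A Square numeric mixing matrix.
#' @return List with `is_valid` (logical) and `D` (integer vector of
#'   per-column argmax row indices).
#' @export
validity_judgment <- function(A) {
  abort_if(!is.matrix(A) || nrow(A) != ncol(A), "`A` must be square")
  aA <- abs(A)
  ties <- 0L
  D <- vapply(seq_len(ncol(aA)), function(h) {
    col <- aA[, h]
    mx <- max(col)
    w <- which(col == mx)
    if (length(w) > 1L) ties <<- ties + 1L
    w[1L]
  }, integer(1))
  if (ties > 0L)
    message(ties, " column maximum tie(s) resolved to the lowest row index")
  list(is_valid = length(unique(D)) == nrow(A), D = D)
}

#' Build an ICA spatial filter bank from trials
#'
#' Fits Infomax ICA to each trial, keeps the filters whose mixing matrices
#' pass the [validity_judgment()], aligns each kept filter so component i
#' corresponds to channel i (rows permuted by the index vector `D`, sign
#' fixed so the peak scalp loading is positive, rows scaled to unit norm),
#' and stores their elementwise mean as the bank's mean filter.
#'
#' @param trials List of numeric channel x sample matrices (or
#'   [eeg_trial()] objects).
#' @param max_iter,tol,lrate Passed to [fit_ica()].
#' @param seed Base seed; trial t uses `seed + t`.
#' @return List of class `spatial_filter_bank` with `valid_filters`,
#'   `mean_filter`, `validity_flags`, `convergence_flags`.
#' @export
build_filter_bank <- function(trials, max_iter = 2000, tol = 1e-9,
                              seed = 1, lrate = 0.1) {
  abort_if(length(trials) < 1, "need at least one trial")
  mats <- lapply(trials, function(tr)
    if (inherits(tr, "eeg_trial")) tr$data else tr)
  n <- nrow(mats[[1]])
  valid <- list()
  vflag <- logical(length(mats))
  cflag <- logical(length(mats))
  for (t in seq_along(mats)) {
    fit <- fit_ica(mats[[t]], max_iter = max_iter, tol = tol,
                   seed = seed + t, lrate = lrate)
    cflag[t] <- fit$converged
    if (!fit$converged) next
    vj <- validity_judgment(fit$A)
    vflag[t] <- vj$is_valid
    if (!vj$is_valid) next
    W <- fit$W
    # Align: component h explains channel D[h]; place its filter row at D[h].
    sgn <- sign(fit$A[cbind(vj$D, seq_len(n))])
    sgn[sgn == 0] <- 1
    Wal <- matrix(0, n, n, dimnames = dimnames(W))
    Wal[vj$D, ] <- W * sgn
    Wal <- Wal / sqrt(rowSums(Wal^2))
    valid[[length(valid) + 1L]] <- Wal
  }
  abort_if(length(valid) == 0,
           "no valid spatial filters were obtained; increase max_iter, ",
           "relax tol, or provide longer/cleaner trials")
  mean_filter <- Reduce(`+`, valid) / length(valid)
  structure(
    list(valid_filters = valid, mean_filter = mean_filter,
         validity_flags = vflag, convergence_flags = cflag),
    class = "spatial_filter_bank"
  )
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat("Spatial filter bank:", length(x$valid_filters), "valid of",
      length(x$validity_flags), "trials (",
      sum(x$convergence_flags), "converged )\n")
  invisible(x)
}

#' SVD spatial features of the mean-filter projection
#'
#' Projects a trial through the bank's mean filter to obtain the component
#' matrix \eqn{\hat S}, takes its singular value decomposition
#' \eqn{\hat S = U \Sigma V^\top}, and returns the spatial features
#' `ES = [lambda_1 v_1, ..., lambda_n v_n]`: each column is a unit right
#' singular vector scaled by its singular value, so column norms equal the
#' (nonincreasing) singular values. Trailing zero singular values from a
#' rank-deficient projection are accepted.
#'
#' @param trial_matrix Numeric channels x samples matrix (or an
#'   [eeg_trial()]).
#' @param bank A [build_filter_bank()] result.
#' @return List of class `spatial_features` with `ES` (samples x channels)
#'   and `singular_values`.
#' @export
extract_spatial_features <- function(trial_matrix, bank) {
  stopifnot(inherits(bank, "spatial_filter_bank"))
  x <- if (inherits(trial_matrix, "eeg_trial")) trial_matrix$data else
    trial_matrix
  abort_if(nrow(x) != nrow(bank$mean_filter),
           "trial channel count does not match the bank")
  S <- bank$mean_filter %*% x
  sv <- svd(S)
  ES <- sv$v %*% diag(sv$d, length(sv$d))
  structure(list(ES = ES, singular_values = sv$d),
            class = "spatial_features")
}

#' Fixed-length summary vector of spatial features
#'
#' Reduces the `ES` matrix to a classifier-ready vector: either the singular
#' values alone (`"lambda_only"`, 30 values for a 30-channel montage) or the
#' singular values followed by the leading scaled singular vector
#' (`"lambda_plus_leading"`).
#'
#' @param sf A [extract_spatial_features()] result.
#' @param mode `"lambda_only"` (default) or `"lambda_plus_leading"`.
#' @return Named numeric vector with attribute `modality = "spatial"`.
#' @export
spatial_feature_vector <- function(sf, mode = c("lambda_only",
                                                "lambda_plus_leading")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sf, "spatial_features"))
  v <- sf$singular_values
  nm <- paste0("lambda_", seq_along(v))
  if (mode == "lambda_plus_leading") {
    lead <- sf$ES[, 1L]
    v <- c(v, lead)
    nm <- c(nm, paste0("es1_", seq_along(lead)))
  }
  feature_vector(v, nm, modality = "spatial")
}
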