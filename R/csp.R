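trial_covariance <- function(X, normalize = FALSE) {
  C <- X %*% t(X)
  if (normalize) C <- C / sum(diag(C))
  C
}

#' Mean spatial covariance of one class
#'
#' The average of the per-trial outer products `T T^T` over the trials of
#' one class. By default no trace normalization is applied; set
#' `normalize = TRUE` to average trace-normalized per-trial covariances
#' instead.
#'
#' @param ts A labeled `trial_set`.
#' @param class Class label (1 or 2).
#' @param normalize Trace-normalize each per-trial covariance first?
#' @return A `class_covariance`: list with `matrix`, `class`, `n_trials`.
#' @export
class_mean_covariance <- function(ts, class, normalize = FALSE) {
  stopifnot(inherits(ts, "trial_set"), !is.null(ts$labels))
  idx <- which(ts$labels == class)
  if (length(idx) == 0L) stop("no trials for class ", class, call. = FALSE)
  nc <- n_channels(ts)
  C <- matrix(0, nc, nc)
  for (i in idx) C <- C + trial_covariance(ts$trials[[i]], normalize)
  C <- C / length(idx)
  structure(list(matrix = (C + t(C)) / 2, class = class,
                 n_trials = length(idx)),
            class = "class_covariance")
}

as_cov_matrix <- function(x) {
  if (inherits(x, "class_covariance")) x$matrix else x
}

#' Fit common spatial pattern filters
#'
#' CSP jointly diagonalizes the two class covariances: the filters are the
#' eigenvectors of `solve(C2) %*% C1`, and the filtered variance ratio
#' between classes equals the corresponding eigenvalue. The eigenproblem is
#' solved in its symmetric-definite generalized form (whitening by the
#' composite covariance `C1 + C2`) for numerical stability; each filter `w`
#' is scaled so that `t(w) %*% (C1 + C2) %*% w = 1`. The bank keeps the `m`
#' largest-eigenvalue filters (descending) followed by the `m`
#' smallest-eigenvalue filters (ascending).
#'
#' @param c1,c2 `class_covariance` objects (or plain symmetric matrices) for
#'   classes 1 and 2.
#' @param m Number of filter pairs (default 3); requires `2 * m <=`
#'   channel count.
#' @param eigen_floor Relative floor applied to the composite covariance's
#'   eigenvalues (default `1e-10`).
#' @return A `csp_filters` object: `filters` (`n_channels x 2m`, columns are
#'   spatial filters), `eigenvalues` (the `2m` variance-ratio eigenvalues of
#'   `solve(C2) %*% C1`) and `m`.
#' @export
fit_csp <- function(c1, c2, m = 3L, eigen_floor = 1e-10) {
  C1 <- as_cov_matrix(c1)
  C2 <- as_cov_matrix(c2)
  nc <- nrow(C1)
  stopifnot(all(dim(C1) == c(nc, nc)), all(dim(C2) == c(nc, nc)))
  if (2L * m > nc) {
    stop("2*m exceeds the number of channels", call. = FALSE)
  }
  Cc <- (C1 + C2 + t(C1) + t(C2)) / 2
  ec <- eigen(Cc, symmetric = TRUE)
  lam_max <- max(ec$values)
  if (lam_max <= 0) stop("composite covariance is degenerate", call. = FALSE)
  if (min(ec$values) < lam_max * 1e-12) {
    warning("composite covariance is near-singular; eigenvalues floored")
  }
  lam <- pmax(ec$values, eigen_floor * lam_max)
  Wh <- ec$vectors %*% diag(1 / sqrt(lam), nrow = nc) %*% t(ec$vectors)
  S1 <- Wh %*% ((C1 + t(C1)) / 2) %*% Wh
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)  # mu in (0, 1), descending
  W <- Wh %*% e1$vectors                            # t(W) (C1+C2) W = I
  mu <- pmin(pmax(e1$values, 1e-15), 1 - 1e-15)
  ratio <- mu / (1 - mu)                            # eigenvalues of C2^-1 C1
  sel <- c(seq_len(m), seq.int(nc, nc - m + 1L))    # m largest desc, m smallest asc
  W <- W[, sel, drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(ncol(W))) {
    peak <- which.max(abs(W[, j]))
    if (W[peak, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(filters = W, eigenvalues = ratio[sel], m = as.integer(m)),
            class = "csp_filters")
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf("<csp_filters: %d channels, m = %d, eigenvalues %s>\n",
              nrow(x$filters), x$m,
              paste(signif(x$eigenvalues, 3), collapse = ", ")))
  invisible(x)
}

#' Log-variance CSP features for one trial
#'
#' Projects the trial through the filter bank and returns the elementwise
#' log of the filtered variances — the diagonal of `W^T C W` with `C` the
#' single-trial covariance (same estimator as the class means). Optionally
#' the variances are normalized by their sum before the log.
#'
#' @param filters A `csp_filters` object.
#' @param X A `n_channels x n_samples` trial matrix.
#' @param normalize_sum Divide filtered variances by their total first?
#'   (off by default).
#' @return Numeric feature vector of length `2 * m`.
#' @export
extract_features <- function(filters, X, normalize_sum = FALSE) {
  stopifnot(inherits(filters, "csp_filters"), is.matrix(X),
            nrow(X) == nrow(filters$filters))
  P <- t(filters$filters) %*% X
  v <- rowSums(P^2)  # diag of W^T X X^T W
  if (normalize_sum) v <- v / sum(v)
  if (any(v <= 0)) {
    stop("zero-variance filtered channel: log-variance feature undefined",
         call. = FALSE)
  }
  log(v)
}

#' Feature matrix for a whole trial set
#'
#' @param filters A `csp_filters` object.
#' @param ts A `trial_set`.
#' @param normalize_sum Passed to [extract_features()].
#' @return A `n_trials x 2m` numeric matrix.
#' @export
extract_feature_matrix <- function(filters, ts, normalize_sum = FALSE) {
  stopifnot(inherits(ts, "trial_set"))
  t(vapply(ts$trials, function(X) extract_features(filters, X, normalize_sum),
           numeric(2L * filters$m)))
}
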