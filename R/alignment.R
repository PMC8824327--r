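#' Reference covariance of a trial set
#'
#' The Euclidean-alignment reference matrix: the arithmetic mean of the
#' trial outer products, `R = (1/I) * sum_i X_i X_i^T`. No label information
#' is used.
#'
#' @param ts A `trial_set` with at least one trial.
#' @param eigen_floor Relative eigenvalue floor used later when inverting
#'   (default `1e-10`, scaled by the largest eigenvalue).
#' @return A `reference_covariance`: list with `matrix` and `eigen_floor`.
#' @export
compute_reference <- function(ts, eigen_floor = 1e-10) {
  stopifnot(inherits(ts, "trial_set"), length(ts$trials) >= 1L)
  nc <- n_channels(ts)
  R <- matrix(0, nc, nc)
  for (X in ts$trials) R <- R + X %*% t(X)
  R <- R / length(ts$trials)
  R <- (R + t(R)) / 2
  structure(list(matrix = R, eigen_floor = eigen_floor),
            class = "reference_covariance")
}

#' Symmetric inverse square root of a reference covariance
#'
#' Computed by eigendecomposition with eigenvalues floored at
#' `eigen_floor * max(eigenvalue)` for numerical stability with few-trial
#' references. For a non-degenerate reference `R`, the result `M` satisfies
#' `M %*% R %*% M = I`.
#'
#' @param ref A `reference_covariance` (or a plain symmetric matrix).
#' @return A symmetric matrix.
#' @export
invert_sqrt <- function(ref) {
  if (inherits(ref, "reference_covariance")) {
    R <- ref$matrix
    floor_rel <- ref$eigen_floor
  } else {
    R <- ref
    floor_rel <- 1e-10
  }
  stopifnot(is.matrix(R), nrow(R) == ncol(R),
            max(abs(R - t(R))) < 1e-8 * max(1, max(abs(R))))
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam_max <- max(e$values)
  if (lam_max <= 0) {
    stop("degenerate reference covariance: no positive eigenvalues", call. = FALSE)
  }
  lam <- pmax(e$values, floor_rel * lam_max)
  e$vectors %*% diag(1 / sqrt(lam), nrow = length(lam)) %*% t(e$vectors)
}

#' Euclidean alignment of a trial set
#'
#' Whitens every trial by the inverse square root of the reference
#' covariance: `X_i -> R^(-1/2) X_i`. Afterwards the mean covariance of the
#' set is the identity matrix, so the trial covariances of different sessions
#' are brought to a common reference while their relative distances are
#' preserved. Alignment is unsupervised: labels are neither used nor
#' modified.
#'
#' @param ts A `trial_set`.
#' @param reference Optional `reference_covariance` to align against (for
#'   example the training-set reference applied to a test set). By default
#'   the set's own reference is computed and used.
#' @return The aligned `trial_set` (`aligned` flag set; labels, order and
#'   shapes preserved).
#' @examples
#' ts <- generate_session(make_subject(generator_config(seed = 1)), 5)
#' mean_cov <- compute_reference(align_trials(ts))$matrix
#' max(abs(mean_cov - diag(nrow(mean_cov))))
#' @export
align_trials <- function(ts, reference = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(reference)) reference <- compute_reference(ts)
  M <- invert_sqrt(reference)
  out <- ts
  out$trials <- lapply(ts$trials, function(X) M %*% X)
  out$aligned <- TRUE
  out
}
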