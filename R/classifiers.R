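#' Fit a linear discriminant analysis classifier (closed form)
#'
#' Two-class LDA with the classical closed form: normal vector
#' `a = solve(C) %*% (m1 - m2)` and intercept `b = -0.5 * t(m1 + m2) %*% a`,
#' where `m1`, `m2` are the class mean feature vectors and `C` is the
#' within-class covariance — pooled over the two classes and weighted by
#' class sizes by default, or the total covariance with `pooled = FALSE`.
#' A small diagonal shrinkage (`1e-6 * trace/d`) keeps `C` invertible for
#' tiny training sets.
#'
#' @param features `n x d` numeric matrix, one row per trial.
#' @param labels Integer class labels in `{1, 2}`.
#' @param pooled Use pooled within-class covariance (default) or total.
#' @return An `lda_model`: `normal`, `intercept`, `class_means`,
#'   `pooled_covariance`.
#' @export
fit_lda <- function(features, labels, pooled = TRUE) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), all(labels %in% c(1L, 2L)))
  i1 <- labels == 1L
  i2 <- labels == 2L
  if (!any(i1) || !any(i2)) stop("both classes must be present", call. = FALSE)
  m1 <- colMeans(features[i1, , drop = FALSE])
  m2 <- colMeans(features[i2, , drop = FALSE])
  d <- ncol(features)
  if (pooled) {
    center <- function(M, mu) sweep(M, 2, mu)
    S <- crossprod(center(features[i1, , drop = FALSE], m1)) +
      crossprod(center(features[i2, , drop = FALSE], m2))
    dof <- max(1L, nrow(features) - 2L)
    C <- S / dof
  } else {
    C <- stats::cov(features)
    C[is.na(C)] <- 0
  }
  gamma <- 1e-6 * sum(diag(C)) / d
  C <- C + diag(max(gamma, 1e-12), d)
  a <- tryCatch(solve(C, m1 - m2),
                error = function(e) stop("degenerate feature covariance",
                                         call. = FALSE))
  b <- -0.5 * sum((m1 + m2) * a)
  structure(list(normal = a, intercept = b,
                 class_means = list(m1 = m1, m2 = m2),
                 pooled_covariance = C),
            class = "lda_model")
}

#' Classification score and label under an LDA model
#'
#' Score `s = t(a) %*% f + b`; the trial is assigned to class 1 when the
#' score is positive and to class 2 otherwise (a score of exactly zero goes
#' to class 2).
#'
#' @param model An `lda_model`.
#' @param f Feature vector, or an `n x d` matrix of feature rows.
#' @return List with numeric `score` and integer `label` (vectors for
#'   matrix input).
#' @export
score_lda <- function(model, f) {
  stopifnot(inherits(model, "lda_model"))
  f <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  stopifnot(ncol(f) == length(model$normal))
  s <- drop(f %*% model$normal) + model$intercept
  list(score = s, label = ifelse(s > 0, 1L, 2L))
}

lr_objective <- function(w, b, F, y, l2) {
  z <- y * (drop(F %*% w) + b)
  # log(1 + exp(-z)) computed stably
  sum(ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))) + l2 / 2 * sum(w^2)
}

#' Fit a two-class logistic regression classifier
#'
#' Minimizes the negative log-likelihood
#' `sum(log(1 + exp(-y_i * (t(w) %*% f_i + b))))` over labels `y` in
#' `{+1, -1}` (mapped internally from `{1, 2}`: class 1 -> +1, class 2 ->
#' -1), plus an optional ridge penalty `l2_penalty/2 * ||w||^2` on the
#' weights only. Fitting is damped Newton from a zero start: the full
#' Newton step is halved until the objective does not increase, so the
#' objective is non-increasing across iterations. Convergence is declared
#' when the gradient norm drops below `tolerance`.
#'
#' @param features `n x d` numeric matrix.
#' @param labels Class labels in `{1, 2}` (or directly in `{+1, -1}`).
#' @param l2_penalty Ridge penalty on `w` (default `1e-6`, a numerical
#'   safeguard so separable small samples cannot diverge; set to 0 for the
#'   plain likelihood).
#' @param tolerance Gradient-norm convergence threshold (default `1e-8`).
#' @param max_iterations Newton iteration cap (default 1000).
#' @return An `lr_model`: `weights`, `intercept`, `converged`, `iterations`,
#'   `objective`.
#' @export
fit_lr <- function(features, labels, l2_penalty = 1e-6, tolerance = 1e-8,
                   max_iterations = 1000L) {
  F <- as.matrix(features)
  stopifnot(nrow(F) == length(labels))
  if (all(labels %in% c(1L, 2L))) {
    y <- ifelse(labels == 1L, 1, -1)
  } else if (all(labels %in% c(-1, 1))) {
    y <- as.numeric(labels)
  } else stop("labels must be in {1, 2} or {+1, -1}", call. = FALSE)
  if (length(unique(y)) != 2L) stop("both classes must be present", call. = FALSE)
  d <- ncol(F)
  w <- rep(0, d)
  b <- 0
  obj <- lr_objective(w, b, F, y, l2_penalty)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    z <- y * (drop(F %*% w) + b)
    p <- 1 / (1 + exp(z))          # d/dz of log(1+exp(-z)) is -p
    g_w <- -drop(crossprod(F, y * p)) + l2_penalty * w
    g_b <- -sum(y * p)
    gnorm <- sqrt(sum(g_w^2) + g_b^2)
    if (gnorm < tolerance) {
      converged <- TRUE
      break
    }
    s <- p * (1 - p)               # curvature weights
    Fa <- cbind(F, 1)
    H <- crossprod(Fa * s, Fa)
    diag(H) <- diag(H) + c(rep(l2_penalty, d), 0) + 1e-12
    step <- tryCatch(solve(H, c(g_w, g_b)),
                     error = function(e) c(g_w, g_b) / max(1, gnorm))
    # damped update: halve until the objective does not increase
    alpha <- 1
    repeat {
      w_new <- w - alpha * step[seq_len(d)]
      b_new <- b - alpha * step[d + 1L]
      obj_new <- lr_objective(w_new, b_new, F, y, l2_penalty)
      if (obj_new <= obj + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (obj_new > obj + 1e-12) break  # no descent direction left
    w <- w_new
    b <- b_new
    obj <- obj_new
  }
  if (!converged && it >= max_iterations) {
    warning("logistic regression did not converge; best iterate returned")
  }
  structure(list(weights = w, intercept = b, l2_penalty = l2_penalty,
                 tolerance = tolerance, max_iterations = max_iterations,
                 converged = converged, iterations = it, objective = obj),
            class = "lr_model")
}

#' Score, probability and label under a logistic regression model
#'
#' Score `z = t(w) %*% f + b`, class-1 probability `1 / (1 + exp(-z))`;
#' class 1 when `z > 0`, class 2 otherwise.
#'
#' @param model An `lr_model`.
#' @param f Feature vector or `n x d` matrix.
#' @return List with `score`, `probability` and `label`.
#' @export
predict_lr <- function(model, f) {
  stopifnot(inherits(model, "lr_model"))
  f <- if (is.matrix(f)) f else matrix(f, nrow = 1L)
  stopifnot(ncol(f) == length(model$weights))
  z <- drop(f %*% model$weights) + model$intercept
  list(score = z, probability = 1 / (1 + exp(-z)),
       label = ifelse(z > 0, 1L, 2L))
}

#' Classification accuracy
#'
#' The ratio of correctly classified trials to the total number of trials.
#'
#' @param predicted Integer vector of predicted labels.
#' @param labels Integer vector of true labels, same length.
#' @return Proportion in `[0, 1]`.
#' @export
accuracy <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels), length(labels) >= 1L)
  mean(predicted == labels)
}
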