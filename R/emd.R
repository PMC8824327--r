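#' Locate interior local extrema of a sampled signal
#'
#' Finds strict interior local maxima and minima. A run of equal samples
#' flanked on both sides by lower (higher) values counts as a single maximum
#' (minimum) placed at the run midpoint, with ties broken toward the left.
#' Runs touching either boundary are not extrema.
#'
#' @param x Numeric vector of finite samples.
#' @return A list with integer vectors `maxima` and `minima`, each in
#'   increasing index order (possibly empty).
#' @examples
#' find_extrema(sin(seq(0, 4 * pi, length.out = 200)))
#' @export
find_extrema <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 3L) {
    return(list(maxima = integer(0), minima = integer(0)))
  }
  # compress runs of equal values
  run_start <- c(1L, which(diff(x) != 0) + 1L)
  run_end <- c(run_start[-1L] - 1L, n)
  vals <- x[run_start]
  k <- length(vals)
  maxima <- integer(0)
  minima <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      mid <- (run_start[j] + run_end[j]) %/% 2L  # ties to the left
      if (vals[j] > vals[j - 1L] && vals[j] > vals[j + 1L]) {
        maxima <- c(maxima, mid)
      } else if (vals[j] < vals[j - 1L] && vals[j] < vals[j + 1L]) {
        minima <- c(minima, mid)
      }
    }
  }
  list(maxima = maxima, minima = minima)
}

# mirror the two extrema nearest each boundary across that boundary
mirror_extrema <- function(idx, val, n) {
  k <- length(idx)
  left_i <- 2L - idx[seq_len(min(2L, k))]
  left_v <- val[seq_len(min(2L, k))]
  right_sel <- seq.int(max(1L, k - 1L), k)
  right_i <- 2L * n - idx[right_sel]
  right_v <- val[right_sel]
  ord <- order(c(left_i, idx, right_i))
  list(
    x = c(left_i, idx, right_i)[ord],
    y = c(left_v, val, right_v)[ord]
  )
}

#' Upper and lower envelopes through local extrema
#'
#' Interpolates the maxima (minima) with a natural cubic spline to obtain the
#' upper (lower) envelope over the full support. Before fitting, the two
#' extrema nearest each boundary are mirrored across it, which suppresses the
#' end swings that unconstrained splines produce.
#'
#' @param x Numeric signal.
#' @param maxima,minima Integer index vectors as returned by [find_extrema()].
#'   If omitted they are recomputed from `x`.
#' @return List with numeric vectors `upper` and `lower`, each `length(x)`.
#' @export
compute_envelopes <- function(x, maxima = NULL, minima = NULL) {
  if (is.null(maxima) || is.null(minima)) {
    ext <- find_extrema(x)
    maxima <- ext$maxima
    minima <- ext$minima
  }
  if (length(maxima) < 2L || length(minima) < 2L) {
    stop("too few extrema to build envelopes (need >= 2 maxima and >= 2 minima)",
         call. = FALSE)
  }
  n <- length(x)
  up <- mirror_extrema(maxima, x[maxima], n)
  lo <- mirror_extrema(minima, x[minima], n)
  # duplicate abscissae can arise when a mirrored point lands on an extremum
  up_keep <- !duplicated(up$x)
  lo_keep <- !duplicated(lo$x)
  upper <- stats::splinefun(up$x[up_keep], up$y[up_keep], method = "natural")(seq_len(n))
  lower <- stats::splinefun(lo$x[lo_keep], lo$y[lo_keep], method = "natural")(seq_len(n))
  list(upper = upper, lower = lower)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Test the intrinsic-mode-function conditions
#'
#' A candidate is an IMF when (1) the number of extrema and the number of
#' zero-crossings differ by at most one, and (2) the mean of its upper and
#' lower envelopes is near zero: the RMS of the envelope mean must be below
#' `tol` times the RMS of the candidate.
#'
#' @param h Numeric candidate signal.
#' @param tol Relative envelope-mean tolerance (default 0.05); strict zero is
#'   unreachable in finite precision.
#' @return Logical scalar.
#' @export
is_imf <- function(h, tol = 0.05) {
  stopifnot(all(is.finite(h)))
  ext <- find_extrema(h)
  n_ext <- length(ext$maxima) + length(ext$minima)
  if (length(ext$maxima) < 2L || length(ext$minima) < 2L) {
    return(FALSE)  # envelope-mean condition cannot be met
  }
  n_zc <- count_zero_crossings(h)
  if (abs(n_ext - n_zc) > 1L) return(FALSE)
  env <- compute_envelopes(h, ext$maxima, ext$minima)
  m <- (env$upper + env$lower) / 2
  rms_h <- sqrt(mean(h^2))
  if (rms_h == 0) return(FALSE)
  sqrt(mean(m^2)) < tol * rms_h
}

#' Create a sifting state for one signal
#'
#' @param x Numeric source signal.
#' @return A `sifting_state` list with fields `current`, `candidate`,
#'   `local_mean`, `residual` and `iteration`.
#' @export
new_sifting_state <- function(x) {
  structure(
    list(current = x, candidate = x, local_mean = rep(0, length(x)),
         residual = x, iteration = 0L),
    class = "sifting_state"
  )
}

#' Perform one sifting step
#'
#' Subtracts the envelope mean from the working signal: the new candidate is
#' `current - (upper + lower)/2` and becomes the working signal of the next
#' step.
#'
#' @param state A `sifting_state` from [new_sifting_state()] or a previous
#'   call.
#' @return The updated `sifting_state` (iteration incremented).
#' @export
sift_once <- function(state) {
  stopifnot(inherits(state, "sifting_state"))
  env <- compute_envelopes(state$current)
  m <- (env$upper + env$lower) / 2
  h <- state$current - m
  state$local_mean <- m
  state$candidate <- h
  state$current <- h
  state$iteration <- state$iteration + 1L
  state
}

residual_is_done <- function(r) {
  ext <- find_extrema(r)
  if (length(ext$maxima) < 2L || length(ext$minima) < 2L) return(TRUE)
  d <- diff(r)
  all(d >= 0) || all(d <= 0)
}

#' Empirical mode decomposition by iterative sifting
#'
#' Decomposes a single-channel signal into intrinsic mode functions, extracted
#' from high to low characteristic frequency, plus a final residue. Each IMF
#' is obtained by sifting: repeatedly subtracting the mean of the upper and
#' lower extrema envelopes until the IMF conditions hold and a Cauchy-type
#' criterion SD = sum((h_prev - h)^2) / sum(h_prev^2) falls below `sd_tol`, or
#' the iteration cap is reached. Decomposition stops when the residual is
#' monotonic or has too few extrema, or when `max_imfs` IMFs were extracted.
#'
#' The residue is computed as the signal minus the running sum of emitted
#' IMFs, so the decomposition is exact by construction: the IMFs and the
#' residue always sum back to the input.
#'
#' @param x Numeric signal, length >= 4, all finite.
#' @param max_imfs Maximum number of IMFs to extract (default 10).
#' @param sd_tol Cauchy sifting threshold (default 0.2).
#' @param max_sift Hard cap on sifting iterations per IMF (default 100).
#' @return An `imf_set`: list with `imfs` (list of numeric vectors), `residue`
#'   (numeric vector) and `source_length`.
#' @examples
#' t <- seq(0, 2, by = 1 / 250)
#' d <- emd(sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * t))
#' length(d$imfs)
#' @export
emd <- function(x, max_imfs = 10L, sd_tol = 0.2, max_sift = 100L) {
  stopifnot(is.numeric(x), length(x) >= 4L)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  imfs <- list()
  r <- x
  while (length(imfs) < max_imfs && !residual_is_done(r)) {
    s <- r
    h <- s
    iter <- 0L
    repeat {
      ext <- find_extrema(s)
      if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
      env <- compute_envelopes(s, ext$maxima, ext$minima)
      m <- (env$upper + env$lower) / 2
      h <- s - m
      iter <- iter + 1L
      sd_crit <- sum((s - h)^2) / sum(s^2)
      if (iter >= max_sift) break
      if (sd_crit < sd_tol && imf_counts_ok(h)) break
      s <- h
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  new_imf_set(imfs, residue = x - sum_signals(imfs, length(x)), source = x)
}

imf_counts_ok <- function(h) {
  ext <- find_extrema(h)
  n_ext <- length(ext$maxima) + length(ext$minima)
  abs(n_ext - count_zero_crossings(h)) <= 1L
}

sum_signals <- function(sigs, n) {
  out <- rep(0, n)
  for (s in sigs) out <- out + s
  out
}

new_imf_set <- function(imfs, residue, source = NULL) {
  n <- length(residue)
  stopifnot(all(vapply(imfs, length, 1L) == n))
  structure(
    list(imfs = imfs, residue = residue, source_length = n),
    class = "imf_set"
  )
}

#' Reconstruct a signal from its decomposition
#'
#' Returns the sum of all IMFs plus the residue, which reproduces the source
#' signal exactly (up to floating-point rounding of the summation).
#'
#' @param imfset An `imf_set` from [emd()].
#' @return Numeric vector of length `imfset$source_length`.
#' @export
emd_reconstruct <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  lens <- vapply(imfset$imfs, length, 1L)
  if (length(lens) && any(lens != imfset$source_length)) {
    stop("IMF lengths do not match source length", call. = FALSE)
  }
  sum_signals(imfset$imfs, imfset$source_length) + imfset$residue
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set: %d IMFs + residue, %d samples>\n",
              length(x$imfs), x$source_length))
  invisible(x)
}
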