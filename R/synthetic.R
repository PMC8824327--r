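#' Configuration for the synthetic motor-imagery EEG generator
#'
#' Defaults mirror the scale of a typical two-class motor-imagery
#' preprocessing pipeline: 15 central channels, 250 Hz, 2-second epochs.
#'
#' @param n_channels Number of sensor channels (default 15).
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param trial_seconds Epoch length in seconds (default 2).
#' @param trials_per_class Trials generated per class per session
#'   (default 50).
#' @param erd_depth Event-related desynchronization depth `d` in `[0, 1)`:
#'   the discriminative mu-band source has variance `p` for class 1 and
#'   `p * (1 - d)` for class 2 (default 0.5). `d = 0` gives a null model
#'   with identically distributed classes.
#' @param snr Ratio of mixed source power to 1/f sensor-noise power
#'   (default 1).
#' @param noise_exponent Spectral slope of the 1/f sensor noise (default 1).
#' @param seed Integer seed for subject and session draws.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_channels = 15L, sampling_rate = 250,
                             trial_seconds = 2, trials_per_class = 50L,
                             erd_depth = 0.5, snr = 1, noise_exponent = 1,
                             seed = NULL) {
  n_samp <- trial_seconds * sampling_rate
  stopifnot(n_channels >= 2L, sampling_rate > 0, trial_seconds > 0,
            n_samp == round(n_samp), erd_depth >= 0, erd_depth < 1, snr > 0)
  structure(
    list(n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
         trial_seconds = trial_seconds, n_samples = as.integer(round(n_samp)),
         trials_per_class = as.integer(trials_per_class),
         erd_depth = erd_depth, snr = snr, noise_exponent = noise_exponent,
         seed = seed),
    class = "generator_config"
  )
}

#' Draw a synthetic subject model
#'
#' The subject is a linear forward model: band-limited stochastic sources
#' mixed into sensors by a random orthonormal matrix. Source 1 is the
#' ground-truth discriminative mu-band (8-13 Hz) source whose power is
#' attenuated by the configured ERD depth for class 2; source 2 is a
#' class-neutral beta-band (14-30 Hz) source; the remaining sources are
#' class-neutral with random bands in 4-40 Hz.
#'
#' @param config A `generator_config`.
#' @return A `subject_model`: `mixing` (orthonormal channels x sources),
#'   `source_bands`, `class_powers` (sources x 2), `discriminative_source`,
#'   `noise_exponent`, `snr`, plus the config.
#' @export
make_subject <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    nc <- config$n_channels
    M <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
    bands <- vector("list", nc)
    bands[[1]] <- c(8, 13)
    bands[[2]] <- c(14, 30)
    nyq <- config$sampling_rate / 2
    for (s in seq_len(nc)[-(1:2)]) {
      lo <- stats::runif(1, 4, min(34, nyq - 8))
      bands[[s]] <- c(lo, lo + stats::runif(1, 4, 10))
    }
    powers <- matrix(1, nc, 2)
    powers[1, 2] <- 1 - config$erd_depth
    structure(
      list(mixing = M, source_bands = bands, class_powers = powers,
           discriminative_source = 1L, noise_exponent = config$noise_exponent,
           snr = config$snr, config = config),
      class = "subject_model"
    )
  })
}

#' Draw a session covariance shift
#'
#' A linear sensor-space perturbation `P = I + magnitude * D` with `D` a
#' fixed random direction of unit Frobenius norm — exactly the class of
#' distortion that Euclidean alignment can correct. Magnitude 0 gives the
#' identity.
#'
#' @param n_channels Channel count.
#' @param magnitude Non-negative scalar (default 0.3).
#' @param seed Optional seed for the direction draw.
#' @return A `session_shift`: `perturbation`, `magnitude`, `direction`.
#' @export
make_shift <- function(n_channels, magnitude = 0.3, seed = NULL) {
  stopifnot(magnitude >= 0)
  with_seed(seed, {
    D <- matrix(stats::rnorm(n_channels^2), n_channels, n_channels)
    D <- D / sqrt(sum(D^2))
    P <- diag(n_channels) + magnitude * D
    if (abs(det(P)) < 1e-8) P <- diag(n_channels) + 0.99 * magnitude * D
    structure(list(perturbation = P, magnitude = magnitude, direction = D),
              class = "session_shift")
  })
}

band_limited_noise <- function(n, fs, band, order = 4L) {
  b <- signal::butter(order, pmin(band / (fs / 2), 0.99), type = "pass")
  pad <- min(n, 200L)
  x <- stats::rnorm(n + 2L * pad)
  y <- signal::filtfilt(b, x)[pad + seq_len(n)]
  y / stats::sd(y)
}

one_over_f_noise <- function(n, exponent) {
  f <- seq_len(floor(n / 2))
  amp <- f^(-exponent / 2)
  phases <- stats::runif(length(f), 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = rep(0, n))
  full[1 + f] <- spec
  full[n + 1 - f] <- Conj(spec)
  if (n %% 2 == 0) full[n / 2 + 1] <- complex(real = amp[length(amp)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

#' Generate one session of synthetic two-class MI trials
#'
#' Per trial: each source is band-limited Gaussian noise scaled by the
#' class-dependent source power, sources are mixed into sensors, 1/f sensor
#' noise is added at the configured SNR, and the whole trial is
#' left-multiplied by the session shift. Class labels alternate 1, 2, 1, 2,
#' ... so sequential prefixes stay balanced.
#'
#' @param model A `subject_model`.
#' @param n_per_class Trials per class.
#' @param shift Optional `session_shift` (default: no shift).
#' @param seed Optional seed for the session draw.
#' @return A labeled `trial_set`.
#' @export
generate_session <- function(model, n_per_class, shift = NULL, seed = NULL) {
  stopifnot(inherits(model, "subject_model"), n_per_class >= 1L)
  cfg <- model$config
  P <- if (is.null(shift)) NULL else shift$perturbation
  with_seed(seed, {
    nc <- cfg$n_channels
    ns <- cfg$n_samples
    labels <- rep(c(1L, 2L), n_per_class)
    trials <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      y <- labels[i]
      S <- matrix(0, nc, ns)
      for (s in seq_len(nc)) {
        S[s, ] <- band_limited_noise(ns, cfg$sampling_rate,
                                     model$source_bands[[s]]) *
          sqrt(model$class_powers[s, y])
      }
      X <- model$mixing %*% S
      sig_var <- mean(X^2)
      noise <- t(vapply(seq_len(nc),
                        function(c) one_over_f_noise(ns, model$noise_exponent),
                        numeric(ns)))
      X <- X + noise * sqrt(sig_var / model$snr)
      if (!is.null(P)) X <- P %*% X
      trials[[i]] <- X
    }
    trial_set(trials, labels = labels, sampling_rate = cfg$sampling_rate)
  })
}

#' Ground-truth discriminative unmixing direction
#'
#' The row of the unmixing (inverse mixing) matrix that isolates the
#' discriminative source, normalized to unit length. The top CSP filter
#' should recover this direction (up to sign) on large-sample data.
#'
#' @param model A `subject_model`.
#' @return Unit-norm numeric vector over channels.
#' @export
ground_truth_direction <- function(model) {
  stopifnot(inherits(model, "subject_model"))
  if (is.null(model$discriminative_source)) {
    stop("model has no discriminative source", call. = FALSE)
  }
  u <- solve(model$mixing)[model$discriminative_source, ]
  u / sqrt(sum(u^2))
}
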