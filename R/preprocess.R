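#' A continuous multichannel recording with event markers
#'
#' @param data `n_channels x n_samples` numeric matrix (microvolts).
#' @param sampling_rate Hz.
#' @param events Data frame with columns `onset` (1-based sample index of
#'   trial start) and `label` (class in `{1, 2}`).
#' @param channel_names Optional channel names.
#' @return A `recording_session`.
#' @export
recording_session <- function(data, sampling_rate, events,
                              channel_names = NULL) {
  stopifnot(is.matrix(data), sampling_rate > 0,
            all(c("onset", "label") %in% names(events)),
            all(events$onset >= 1), all(events$onset <= ncol(data)))
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, sampling_rate = sampling_rate,
                 events = as.data.frame(events),
                 channel_names = channel_names),
            class = "recording_session")
}

butter_bandpass <- function(low, high, fs, order) {
  if (high >= fs / 2) stop("band edge at or above Nyquist frequency", call. = FALSE)
  stopifnot(low > 0, low < high)
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

apply_filter_matrix <- function(X, flt, zero_phase) {
  t(apply(X, 1, function(ch) {
    if (zero_phase) signal::filtfilt(flt, ch) else
      as.numeric(signal::filter(flt, ch))
  }))
}

#' Butterworth band-pass filtering
#'
#' Applies a Butterworth band-pass of the given order per channel; with
#' `zero_phase = TRUE` (the default, appropriate for offline analysis) the
#' filter is run forward and backward so no phase distortion is introduced.
#' Works on a plain matrix, a `recording_session` or a `trial_set`.
#'
#' @param x Matrix (`channels x samples`), `recording_session` or
#'   `trial_set`.
#' @param low,high Band edges in Hz (defaults 8 and 30, the mu + beta
#'   range).
#' @param order Filter order (default 5).
#' @param zero_phase Forward-backward filtering? (default `TRUE`).
#' @param sampling_rate Required for plain-matrix input; taken from the
#'   object otherwise.
#' @return Same type as the input.
#' @export
bandpass_filter <- function(x, low = 8, high = 30, order = 5L,
                            zero_phase = TRUE, sampling_rate = NULL) {
  if (inherits(x, "recording_session")) {
    flt <- butter_bandpass(low, high, x$sampling_rate, order)
    x$data <- apply_filter_matrix(x$data, flt, zero_phase)
    return(x)
  }
  if (inherits(x, "trial_set")) {
    flt <- butter_bandpass(low, high, x$sampling_rate, order)
    x$trials <- lapply(x$trials, apply_filter_matrix, flt = flt,
                       zero_phase = zero_phase)
    return(x)
  }
  stopifnot(is.matrix(x), !is.null(sampling_rate))
  flt <- butter_bandpass(low, high, sampling_rate, order)
  apply_filter_matrix(x, flt, zero_phase)
}

#' Epoch a continuous recording into trials
#'
#' Cuts one trial per event using a half-open window `[start, end)` in
#' seconds relative to the trial start. Events whose window exceeds the
#' recording are skipped with a warning.
#'
#' @param session A `recording_session`.
#' @param window Numeric length-2: `(start, end)` in seconds (e.g.
#'   `c(2.5, 4.5)` to capture the imagery period).
#' @return A labeled `trial_set`.
#' @export
epoch_session <- function(session, window) {
  stopifnot(inherits(session, "recording_session"), length(window) == 2L,
            window[2] > window[1])
  fs <- session$sampling_rate
  n_win <- as.integer(round((window[2] - window[1]) * fs))
  off <- as.integer(round(window[1] * fs))
  trials <- list()
  labels <- integer(0)
  for (i in seq_len(nrow(session$events))) {
    start <- session$events$onset[i] + off
    stop_ <- start + n_win - 1L
    if (start < 1L || stop_ > ncol(session$data)) {
      warning(sprintf("event %d skipped: window outside recording", i))
      next
    }
    trials[[length(trials) + 1L]] <- session$data[, start:stop_, drop = FALSE]
    labels <- c(labels, as.integer(session$events$label[i]))
  }
  if (length(trials) == 0L) stop("no usable events", call. = FALSE)
  trial_set(trials, labels = labels, channel_names = session$channel_names,
            sampling_rate = fs)
}

#' The 15 central channels of the standard 22-channel MI montage
#'
#' C3, Cz, C4 and their neighbors: the central 3 x 5 grid (frontocentral,
#' central and centroparietal rows) over the sensorimotor cortex.
#'
#' @return Character vector of 15 channel names.
#' @export
central_channels_22 <- function() {
  c("FC3", "FC1", "FCz", "FC2", "FC4",
    "C3",  "C1",  "Cz",  "C2",  "C4",
    "CP3", "CP1", "CPz", "CP2", "CP4")
}

#' The standard 22-channel MI montage labels
#'
#' @return Character vector of 22 channel names.
#' @export
montage_22 <- function() {
  c("Fz",
    "FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    "P1", "Pz", "P2", "POz")
}

#' Retain a named subset of channels
#'
#' @param ts A `trial_set`.
#' @param channels Character vector of channel names to keep, in the order
#'   they should appear (default: the 15 central channels of the
#'   22-channel montage).
#' @return A `trial_set` with exactly the requested channels.
#' @export
select_channels <- function(ts, channels = central_channels_22()) {
  stopifnot(inherits(ts, "trial_set"))
  missing <- setdiff(channels, ts$channel_names)
  if (length(missing)) {
    stop("montage lacks channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(channels, ts$channel_names)
  out <- ts
  out$trials <- lapply(ts$trials, function(X) X[idx, , drop = FALSE])
  out$channel_names <- channels
  out
}
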