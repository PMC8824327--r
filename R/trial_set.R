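#' Construct a set of epoched EEG trials
#'
#' The central data container: an ordered collection of epoched trials, each
#' a channels x samples matrix in microvolts, with optional two-class labels.
#'
#' @param trials List of numeric matrices, all `n_channels x n_samples`.
#' @param labels Optional integer vector of per-trial class labels in
#'   `{1, 2}` (length = number of trials), or `NULL` for unlabeled sets.
#' @param channel_names Character vector of channel names (defaults to
#'   `"ch1"..."chN"`).
#' @param sampling_rate Sampling rate in Hz.
#' @param aligned Logical: has Euclidean alignment been applied?
#' @param provenance Optional character vector, `"real"` or `"artificial"`
#'   per trial.
#' @return A `trial_set` object.
#' @export
trial_set <- function(trials, labels = NULL, channel_names = NULL,
                      sampling_rate = 250, aligned = FALSE,
                      provenance = NULL) {
  stopifnot(is.list(trials), length(trials) >= 1L, sampling_rate > 0)
  dims <- vapply(trials, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all trials must share the same channel and sample counts", call. = FALSE)
  }
  n_ch <- dims[1, 1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  stopifnot(length(channel_names) == n_ch)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(trials))
    if (!all(labels %in% c(1L, 2L))) {
      stop("labels must be in {1, 2}", call. = FALSE)
    }
    labels <- as.integer(labels)
  }
  if (is.null(provenance)) provenance <- rep("real", length(trials))
  stopifnot(length(provenance) == length(trials),
            all(provenance %in% c("real", "artificial")))
  structure(
    list(trials = trials, labels = labels, channel_names = channel_names,
         sampling_rate = sampling_rate, aligned = isTRUE(aligned),
         provenance = provenance),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials[[1]])
  cat(sprintf("<trial_set: %d trials, %d channels x %d samples @ %g Hz%s%s>\n",
              length(x$trials), d[1], d[2], x$sampling_rate,
              if (is.null(x$labels)) ", unlabeled" else
                sprintf(", classes %d/%d", sum(x$labels == 1L), sum(x$labels == 2L)),
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' @export
length.trial_set <- function(x) length(x$trials)

n_channels <- function(ts) nrow(ts$trials[[1]])
n_samples <- function(ts) ncol(ts$trials[[1]])

#' Subset a trial set by trial index
#'
#' @param ts A `trial_set`.
#' @param idx Integer vector of trial indices.
#' @return A `trial_set` with the selected trials, labels and provenance.
#' @export
subset_trials <- function(ts, idx) {
  stopifnot(inherits(ts, "trial_set"), all(idx >= 1L), all(idx <= length(ts$trials)))
  trial_set(ts$trials[idx],
            labels = if (is.null(ts$labels)) NULL else ts$labels[idx],
            channel_names = ts$channel_names,
            sampling_rate = ts$sampling_rate,
            aligned = ts$aligned,
            provenance = ts$provenance[idx])
}

#' Write a trial set to a plain-text directory
#'
#' The exchange format is a directory with three files: `data.txt`, a flat
#' whitespace-separated numeric matrix with one row per (trial, channel) pair
#' in trial-major order and one column per sample; `labels.txt`, one label
#' per line (`NA` for unlabeled); and `meta.json` with the sampling rate,
#' channel names, alignment flag and provenance.
#'
#' @param ts A `trial_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_set <- function(ts, dir) {
  stopifnot(inherits(ts, "trial_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- do.call(rbind, ts$trials)
  utils::write.table(flat, file.path(dir, "data.txt"),
                     row.names = FALSE, col.names = FALSE)
  labs <- if (is.null(ts$labels)) rep(NA_integer_, length(ts$trials)) else ts$labels
  writeLines(as.character(labs), file.path(dir, "labels.txt"))
  meta <- list(
    n_trials = length(ts$trials),
    n_channels = n_channels(ts),
    n_samples = n_samples(ts),
    sampling_rate = ts$sampling_rate,
    channel_names = ts$channel_names,
    aligned = ts$aligned,
    provenance = ts$provenance
  )
  writeLines(to_json(meta), file.path(dir, "meta.json"))
  invisible(dir)
}

# minimal JSON writer/reader so the package core needs no JSON dependency
to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      paste0("[", paste(vapply(v, enc, ""), collapse = ","), "]")
    } else if (is.character(v)) {
      paste0("[", paste(paste0('"', v, '"'), collapse = ","), "]")
    } else if (is.logical(v)) {
      paste0("[", paste(ifelse(v, "true", "false"), collapse = ","), "]")
    } else {
      paste0("[", paste(format(v, digits = 15, scientific = FALSE), collapse = ","), "]")
    }
  }
  paste0("{", paste(sprintf('"%s":%s', names(x), vapply(x, enc, "")),
                    collapse = ","), "}")
}

#' Read a trial set from a plain-text directory
#'
#' Inverse of [write_trial_set()].
#'
#' @param dir Directory written by [write_trial_set()].
#' @return A `trial_set`.
#' @export
read_trial_set <- function(dir) {
  meta_txt <- paste(readLines(file.path(dir, "meta.json")), collapse = "")
  meta <- parse_meta_json(meta_txt)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.txt")))
  dimnames(flat) <- NULL
  labs <- suppressWarnings(as.integer(readLines(file.path(dir, "labels.txt"))))
  if (all(is.na(labs))) labs <- NULL
  trials <- lapply(seq_len(meta$n_trials), function(i) {
    flat[(i - 1L) * meta$n_channels + seq_len(meta$n_channels), , drop = FALSE]
  })
  trial_set(trials, labels = labs, channel_names = meta$channel_names,
            sampling_rate = meta$sampling_rate, aligned = meta$aligned,
            provenance = meta$provenance)
}

parse_meta_json <- function(txt) {
  grab <- function(key) {
    m <- regmatches(txt, regexec(sprintf('"%s":\\[([^]]*)\\]', key), txt))[[1]][2]
    strsplit(m, ",", fixed = TRUE)[[1]]
  }
  num <- function(key) as.numeric(grab(key))
  chr <- function(key) gsub('"', "", grab(key), fixed = TRUE)
  list(
    n_trials = as.integer(num("n_trials")),
    n_channels = as.integer(num("n_channels")),
    n_samples = as.integer(num("n_samples")),
    sampling_rate = num("sampling_rate"),
    channel_names = chr("channel_names"),
    aligned = identical(chr("aligned"), "true"),
    provenance = chr("provenance")
  )
}
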