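# run code with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Decompose every channel of every trial into its leading IMFs
#'
#' Applies [emd()] to each channel of each labeled trial and retains the
#' first `n_imfs` intrinsic mode functions per channel. Channels that yield
#' fewer than `n_imfs` IMFs are padded with zero sequences and flagged.
#' Residues are kept out of the bank: only IMFs take part in synthesis.
#'
#' @param ts A labeled `trial_set`.
#' @param n_imfs Number of leading IMFs to retain per channel (default 5;
#'   the first five IMFs carry the bulk of the motor-imagery-related
#'   information).
#' @param ... Passed on to [emd()].
#' @return An `imf_bank`: per class, a list of per-trial arrays with
#'   dimensions `(n_imfs, n_samples, n_channels)`, plus padding flags.
#' @export
decompose_trials <- function(ts, n_imfs = 5L, ...) {
  stopifnot(inherits(ts, "trial_set"), n_imfs >= 1L)
  if (is.null(ts$labels)) {
    stop("decompose_trials() requires a labeled trial_set", call. = FALSE)
  }
  ns <- n_samples(ts)
  nc <- n_channels(ts)
  per_class <- lapply(c(1L, 2L), function(y) {
    idx <- which(ts$labels == y)
    stacks <- vector("list", length(idx))
    padded <- matrix(FALSE, length(idx), nc)
    for (j in seq_along(idx)) {
      A <- array(0, dim = c(n_imfs, ns, nc))
      X <- ts$trials[[idx[j]]]
      for (c in seq_len(nc)) {
        dec <- emd(X[c, ], max_imfs = n_imfs, ...)
        k <- length(dec$imfs)
        for (m in seq_len(min(k, n_imfs))) A[m, , c] <- dec$imfs[[m]]
        if (k < n_imfs) padded[j, c] <- TRUE
      }
      stacks[[j]] <- A
    }
    list(stacks = stacks, zero_padded = padded)
  })
  structure(
    list(class1 = per_class[[1]], class2 = per_class[[2]], n_imfs = n_imfs,
         n_samples = ns, n_channels = nc, channel_names = ts$channel_names,
         sampling_rate = ts$sampling_rate, aligned = ts$aligned),
    class = "imf_bank"
  )
}

bank_class <- function(bank, class) {
  stopifnot(class %in% c(1L, 2L))
  if (class == 1L) bank$class1 else bank$class2
}

#' Synthesize one artificial trial from an IMF bank
#'
#' Draws an ordered selection of `n_imfs` donor trials from the requested
#' class (without replacement when the class holds at least `n_imfs` trials,
#' with replacement otherwise) and sums, per channel, the k-th IMF of the
#' k-th drawn donor. The same donor assignment is shared by all channels, so
#' each IMF slot contributes a spatially coherent multichannel component.
#'
#' @param bank An `imf_bank` from [decompose_trials()].
#' @param class Class label (1 or 2).
#' @return A `n_channels x n_samples` matrix.
#' @export
synthesize_trial <- function(bank, class) {
  stopifnot(inherits(bank, "imf_bank"))
  cls <- bank_class(bank, class)
  pool <- length(cls$stacks)
  if (pool < 1L) stop("no trials available for this class", call. = FALSE)
  k <- bank$n_imfs
  donors <- sample.int(pool, k, replace = pool < k)
  out <- matrix(0, bank$n_channels, bank$n_samples)
  for (m in seq_len(k)) {
    out <- out + t(cls$stacks[[donors[m]]][m, , ])
  }
  out
}

#' Augment a training set with artificial trials
#'
#' Generates `multiple` artificial trials per real trial of each class by
#' random within-class IMF recombination and pools them with the originals.
#' Real trials precede artificial trials in the output; provenance is
#' recorded per trial. With `multiple = 0` the input is returned unchanged
#' (and no decomposition is performed).
#'
#' @param ts A labeled `trial_set` with both classes present.
#' @param multiple Non-negative integer: artificial trials per class =
#'   `multiple` x real trials per class.
#' @param n_imfs IMFs retained per channel (default 5).
#' @param seed Integer seed making the draw reproducible, or `NULL` to use
#'   the current RNG stream.
#' @param bank Optional precomputed `imf_bank` for `ts` (skips the EMD pass;
#'   useful when sweeping several multiples over the same trials).
#' @return The augmented `trial_set`; attribute `"augment_spec"` records
#'   `multiple`, `n_imfs` and `seed`.
#' @export
augment_trials <- function(ts, multiple, n_imfs = 5L, seed = NULL, bank = NULL) {
  stopifnot(inherits(ts, "trial_set"))
  if (!is.numeric(multiple) || length(multiple) != 1L || multiple < 0 ||
      multiple != round(multiple)) {
    stop("multiple must be a non-negative integer", call. = FALSE)
  }
  if (is.null(ts$labels) || length(unique(ts$labels)) != 2L) {
    stop("augment_trials() requires both classes in a labeled trial_set",
         call. = FALSE)
  }
  multiple <- as.integer(multiple)
  out <- ts
  if (multiple > 0L) {
    if (is.null(bank)) bank <- decompose_trials(ts, n_imfs = n_imfs)
    art <- with_seed(seed, {
      res <- list(trials = list(), labels = integer(0))
      for (y in c(1L, 2L)) {
        n_real <- length(bank_class(bank, y)$stacks)
        for (i in seq_len(multiple * n_real)) {
          res$trials[[length(res$trials) + 1L]] <- synthesize_trial(bank, y)
          res$labels <- c(res$labels, y)
        }
      }
      res
    })
    out <- trial_set(
      c(ts$trials, art$trials),
      labels = c(ts$labels, art$labels),
      channel_names = ts$channel_names,
      sampling_rate = ts$sampling_rate,
      aligned = ts$aligned,
      provenance = c(ts$provenance, rep("artificial", length(art$trials)))
    )
  }
  attr(out, "augment_spec") <- list(multiple = multiple, n_imfs = n_imfs,
                                    seed = seed)
  out
}

#' Build the family of augmented training collections
#'
#' One augmented collection per requested multiple, in increasing order. A
#' single EMD pass over the input is shared by all collections. With the
#' default `multiples = 0:10` this yields 11 collections, the first being
#' the raw training set.
#'
#' @param ts A labeled `trial_set`.
#' @param multiples Integer vector of multiples (default `0:10`).
#' @param n_imfs IMFs retained per channel (default 5).
#' @param seed Base seed; collection for multiple m uses `seed + m`.
#' @return Named list of `trial_set`s (`"m0"`, `"m1"`, ...).
#' @export
build_collections <- function(ts, multiples = 0:10, n_imfs = 5L, seed = NULL) {
  stopifnot(length(multiples) >= 1L)
  multiples <- sort(unique(as.integer(multiples)))
  bank <- if (any(multiples > 0L)) decompose_trials(ts, n_imfs = n_imfs) else NULL
  out <- lapply(multiples, function(m) {
    augment_trials(ts, m, n_imfs = n_imfs,
                   seed = if (is.null(seed)) NULL else seed + m, bank = bank)
  })
  names(out) <- paste0("m", multiples)
  out
}
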