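#' Sequential training subset
#'
#' Takes the first `n_per_class` trials of each class, in their original
#' order — imitating an online calibration session where trials accumulate
#' sequentially.
#'
#' @param ts A labeled `trial_set`.
#' @param n_per_class Trials to keep per class.
#' @return A `trial_set`.
#' @export
sequential_train_subset <- function(ts, n_per_class) {
  stopifnot(inherits(ts, "trial_set"), !is.null(ts$labels))
  idx <- unlist(lapply(c(1L, 2L), function(y) {
    w <- which(ts$labels == y)
    if (length(w) < n_per_class) {
      stop(sprintf("class %d has only %d trials (need %d)", y, length(w),
                   n_per_class), call. = FALSE)
    }
    w[seq_len(n_per_class)]
  }))
  subset_trials(ts, sort(idx))
}

fit_and_score <- function(train, test, classifier, csp_m, normalize_cov = FALSE) {
  c1 <- class_mean_covariance(train, 1L, normalize = normalize_cov)
  c2 <- class_mean_covariance(train, 2L, normalize = normalize_cov)
  filters <- fit_csp(c1, c2, m = csp_m)
  Ftr <- extract_feature_matrix(filters, train)
  Fte <- extract_feature_matrix(filters, test)
  if (classifier == "lda") {
    model <- fit_lda(Ftr, train$labels)
    pred <- score_lda(model, Fte)
  } else if (classifier == "lr") {
    model <- fit_lr(Ftr, train$labels)
    pred <- predict_lr(model, Fte)
  } else stop("unknown classifier: ", classifier, call. = FALSE)
  list(accuracy = accuracy(pred$label, test$labels), model = model,
       filters = filters, scores = pred$score)
}

#' Run one classification method end to end
#'
#' The three compared methods, on preprocessed and channel-selected trial
#' sets:
#' * `"baseline"` — CSP + classifier on the raw training subset (no
#'   artificial trials; `multiple` is ignored);
#' * `"emd"` — IMF-recombination augmentation of the raw training subset at
#'   the given multiple, then CSP + classifier;
#' * `"ea_emd"` — Euclidean alignment of both sets, augmentation of the
#'   aligned training subset, then CSP + classifier.
#'
#' Artificial trials take part in the CSP class covariances and classifier
#' training alongside the real trials. Accuracy is measured on the test set.
#'
#' @param train,test Labeled `trial_set`s with matching channels.
#' @param method `"baseline"`, `"emd"` or `"ea_emd"`.
#' @param multiple Artificial-to-real multiple (0-10 in the reference
#'   protocol).
#' @param classifier `"lda"` or `"lr"`.
#' @param csp_m CSP filter pairs (default 3).
#' @param seed Seed for the augmentation donor draws.
#' @param n_imfs IMFs retained per channel (default 5).
#' @param test_reference For `"ea_emd"`: `"self"` (default) aligns the test
#'   set with its own reference, `"train"` reuses the training reference.
#' @param bank Optional precomputed `imf_bank` of the (aligned, for
#'   `"ea_emd"`) training subset, to share one EMD pass across multiples.
#' @return Accuracy in `[0, 1]`.
#' @export
run_method <- function(train, test, method = c("baseline", "emd", "ea_emd"),
                       multiple = 0L, classifier = c("lda", "lr"),
                       csp_m = 3L, seed = NULL, n_imfs = 5L,
                       test_reference = c("self", "train"), bank = NULL) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  test_reference <- match.arg(test_reference)
  if (method == "baseline") {
    return(fit_and_score(train, test, classifier, csp_m)$accuracy)
  }
  if (method == "ea_emd") {
    ref_train <- compute_reference(train)
    train <- align_trials(train, ref_train)
    test <- if (test_reference == "train") align_trials(test, ref_train)
            else align_trials(test)
  }
  aug <- augment_trials(train, multiple, n_imfs = n_imfs, seed = seed,
                        bank = bank)
  fit_and_score(aug, test, classifier, csp_m)$accuracy
}

#' Learning curve over training-set sizes and augmentation multiples
#'
#' Sweeps the number of (sequentially chosen) training trials per class and
#' the artificial-frame multiple for each requested method, and reports the
#' full accuracy grid plus the best multiple per (method, n_train) cell.
#' Best-multiple selection is either `"oracle"` (the multiple with the
#' highest test accuracy — the replication convention, optimistically
#' biased) or `"cv"` (chosen on a split of the training data only).
#'
#' @param train,test Labeled `trial_set`s.
#' @param n_train_grid Training trials per class to evaluate (default
#'   `seq(5, 50, by = 5)`).
#' @param multiples Multiples to evaluate (default `0:10`; baseline always
#'   uses 0 only).
#' @param methods Methods to compare (default all three).
#' @param classifier `"lda"` or `"lr"`.
#' @param csp_m CSP filter pairs.
#' @param seed Base seed for augmentation draws.
#' @param n_imfs IMFs per channel.
#' @param multiple_selection `"oracle"` or `"cv"`.
#' @return A tibble with columns `method`, `n_train`, `multiple`,
#'   `accuracy`, `best` (logical: selected multiple for that cell).
#' @export
learning_curve <- function(train, test, n_train_grid = seq(5, 50, by = 5),
                           multiples = 0:10,
                           methods = c("baseline", "emd", "ea_emd"),
                           classifier = c("lda", "lr"), csp_m = 3L,
                           seed = 1L, n_imfs = 5L,
                           multiple_selection = c("oracle", "cv")) {
  classifier <- match.arg(classifier)
  multiple_selection <- match.arg(multiple_selection)
  stopifnot(length(n_train_grid) >= 1L, length(multiples) >= 1L)
  rows <- list()
  for (n_tr in n_train_grid) {
    sub <- sequential_train_subset(train, n_tr)
    for (method in methods) {
      mults <- if (method == "baseline") 0L else sort(unique(as.integer(multiples)))
      bank <- NULL
      tr_m <- sub
      te_m <- test
      if (method == "ea_emd") {
        tr_m <- align_trials(sub)
        te_m <- align_trials(test)
      }
      if (method != "baseline" && any(mults > 0L)) {
        bank <- decompose_trials(tr_m, n_imfs = n_imfs)
      }
      accs <- vapply(mults, function(mlt) {
        if (mlt == 0L) {
          fit_and_score(tr_m, te_m, classifier, csp_m)$accuracy
        } else {
          aug <- augment_trials(tr_m, mlt, n_imfs = n_imfs,
                                seed = seed + mlt, bank = bank)
          fit_and_score(aug, te_m, classifier, csp_m)$accuracy
        }
      }, numeric(1))
      best_idx <- if (multiple_selection == "oracle" || method == "baseline") {
        which.max(accs)
      } else {
        cv_pick_multiple(tr_m, mults, bank, classifier, csp_m, seed, n_imfs)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method, n_train = n_tr, multiple = mults, accuracy = accs,
        best = seq_along(mults) == best_idx
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "classifier") <- classifier
  attr(out, "multiple_selection") <- multiple_selection
  out
}

# inner holdout on the training subset: first half fits, second half scores
cv_pick_multiple <- function(train, mults, bank, classifier, csp_m, seed,
                             n_imfs) {
  n_half <- max(2L, floor(min(table(train$labels)) / 2))
  inner_tr <- sequential_train_subset(train, n_half)
  rest <- setdiff(seq_along(train$trials),
                  unlist(lapply(c(1L, 2L), function(y)
                    which(train$labels == y)[seq_len(n_half)])))
  if (length(rest) < 2L) return(1L)
  inner_te <- subset_trials(train, rest)
  inner_bank <- if (any(mults > 0L)) decompose_trials(inner_tr, n_imfs = n_imfs)
                else NULL
  accs <- vapply(mults, function(mlt) {
    tr <- if (mlt == 0L) inner_tr else
      augment_trials(inner_tr, mlt, n_imfs = n_imfs, seed = seed + mlt,
                     bank = inner_bank)
    tryCatch(fit_and_score(tr, inner_te, classifier, csp_m)$accuracy,
             error = function(e) NA_real_)
  }, numeric(1))
  which.max(accs)
}

#' Paired t-test between two accuracy vectors
#'
#' Two-sided paired t-test across subjects (or seeds). Zero-variance
#' differences make the statistic undefined and are flagged rather than
#' reported as a p-value.
#'
#' @param acc_a,acc_b Equal-length numeric vectors of paired accuracies.
#' @param alpha Significance level (default 0.05).
#' @return A tibble row: `mean_diff`, `statistic`, `p_value`, `significant`,
#'   `undefined`, `n`, `alpha`.
#' @export
paired_ttest <- function(acc_a, acc_b, alpha = 0.05) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2L)
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    return(tibble::tibble(mean_diff = mean(d), statistic = NA_real_,
                          p_value = NA_real_, significant = NA,
                          undefined = TRUE, n = length(d), alpha = alpha))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  tibble::tibble(mean_diff = mean(d), statistic = unname(tt$statistic),
                 p_value = tt$p.value, significant = tt$p.value < alpha,
                 undefined = FALSE, n = length(d), alpha = alpha)
}

#' Per-trial classification scores for visualization
#'
#' The scalar classifier score of every trial (the output before taking the
#' sign), with predicted label and provenance — the basis for score-scatter
#' plots comparing raw, aligned and augmented training data.
#'
#' @param model An `lda_model` or `lr_model`.
#' @param features `n x d` feature matrix.
#' @param labels Optional true labels.
#' @param provenance Optional per-trial `"real"`/`"artificial"` flags.
#' @return A tibble: `trial`, `score`, `predicted`, and optionally `label`,
#'   `provenance`.
#' @export
export_scores <- function(model, features, labels = NULL, provenance = NULL) {
  features <- as.matrix(features)
  pred <- if (inherits(model, "lda_model")) score_lda(model, features)
          else predict_lr(model, features)
  out <- tibble::tibble(trial = seq_len(nrow(features)),
                        score = pred$score, predicted = pred$label)
  if (!is.null(labels)) out$label <- as.integer(labels)
  if (!is.null(provenance)) out$provenance <- provenance
  out
}

#' Multi-subject synthetic study
#'
#' Draws `n_subjects` synthetic subjects, generates a training session and a
#' covariance-shifted test session for each, and evaluates the requested
#' methods at one training-set size, sweeping the augmentation multiple.
#' This is the desk-scale analogue of a multi-subject calibration-reduction
#' study.
#'
#' @param n_subjects Number of subjects (independent seeds).
#' @param n_train_per_class Training trials per class fed to the methods.
#' @param n_test_per_class Test trials per class (default 50).
#' @param n_train_pool Trials per class generated for the training session
#'   (default `max(n_train_per_class, 10)`), from which the sequential
#'   subset is taken.
#' @param multiples Multiples swept for the augmenting methods (default
#'   `0:10`).
#' @param methods Methods to run (default all three).
#' @param classifier `"lda"` or `"lr"`.
#' @param csp_m CSP filter pairs.
#' @param erd_depth,snr,shift_magnitude Generator parameters (defaults 0.5,
#'   1, 0.3).
#' @param band Band-pass edges in Hz applied to both sessions before
#'   anything else, following the pipeline order filter -> align ->
#'   decompose -> CSP (default `c(8, 30)`; `NULL` skips filtering).
#' @param seed Base seed; subject s uses seeds derived from `seed` and `s`.
#' @return A tibble: `subject`, `method`, `multiple`, `accuracy`, `best`.
#' @export
simulate_study <- function(n_subjects, n_train_per_class,
                           n_test_per_class = 50L,
                           n_train_pool = max(n_train_per_class, 10L),
                           multiples = 0:10,
                           methods = c("baseline", "emd", "ea_emd"),
                           classifier = c("lda", "lr"), csp_m = 3L,
                           erd_depth = 0.5, snr = 1, shift_magnitude = 0.3,
                           band = c(8, 30), seed = 1L) {
  classifier <- match.arg(classifier)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    base <- seed * 1000L + s * 7L
    cfg <- generator_config(erd_depth = erd_depth, snr = snr, seed = base)
    model <- make_subject(cfg)
    shift <- make_shift(cfg$n_channels, shift_magnitude, seed = base + 1L)
    train <- generate_session(model, n_train_pool, seed = base + 2L)
    test <- generate_session(model, n_test_per_class, shift = shift,
                             seed = base + 3L)
    if (!is.null(band)) {
      train <- bandpass_filter(train, band[1], band[2])
      test <- bandpass_filter(test, band[1], band[2])
    }
    lc <- learning_curve(train, test, n_train_grid = n_train_per_class,
                         multiples = multiples, methods = methods,
                         classifier = classifier, csp_m = csp_m,
                         seed = base + 4L)
    lc$subject <- s
    rows[[length(rows) + 1L]] <- lc[, c("subject", "method", "multiple",
                                        "accuracy", "best")]
  }
  do.call(rbind, rows)
}
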