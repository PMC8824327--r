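# tiny tonal trial set: channels are tones with per-trial frequencies
tonal_trial_set <- function(freqs_by_trial, n_channels = 3, fs = 128,
                            seconds = 1) {
  trials <- lapply(freqs_by_trial, function(f) {
    t(vapply(seq_len(n_channels),
             function(c) tone(f + c - 1, seconds, fs),
             numeric(seconds * fs + 1)))
  })
  trial_set(trials, labels = rep(c(1L, 2L), length.out = length(trials)),
            sampling_rate = fs)
}

test_that("decompose_trials keeps shapes and flags zero-padded channels", {
  ts <- tonal_trial_set(c(10, 12, 14, 16))  # pure-ish tones: few IMFs
  bank <- decompose_trials(ts, n_imfs = 5)
  expect_s3_class(bank, "imf_bank")
  expect_length(bank$class1$stacks, 2)
  expect_length(bank$class2$stacks, 2)
  expect_identical(dim(bank$class1$stacks[[1]]), c(5L, 129L, 3L))
  # pure tones decompose into < 5 IMFs, so padding must be flagged
  expect_true(any(bank$class1$zero_padded))
  # padded slots are exactly zero
  A <- bank$class1$stacks[[1]]
  d <- emd(ts$trials[[1]][1, ], max_imfs = 5)
  if (length(d$imfs) < 5) {
    expect_true(all(A[5, , 1] == 0))
  }
  # IMF 1 of a pure tone is close to the input channel
  ctr <- 13:116
  expect_gt(cor(A[1, ctr, 1], ts$trials[[1]][1, ctr]), 0.99)

  unlab <- ts
  unlab$labels <- NULL
  expect_error(decompose_trials(unlab), "labeled")
})

test_that("synthesis from a single-trial bank is the forced IMF sum", {
  ts <- tonal_trial_set(c(9, 11))
  bank <- decompose_trials(ts, n_imfs = 5)
  set.seed(1)
  art <- synthesize_trial(bank, 1L)
  expected <- matrix(0, 3, 129)
  for (k in 1:5) expected <- expected + t(bank$class1$stacks[[1]][k, , ])
  expect_equal(art, expected, tolerance = 1e-12)
})

test_that("synthesis draws one donor assignment shared across channels", {
  ts <- random_trial_set(n_per_class = 6, n_channels = 3, n_samples = 128,
                         seed = 21)
  bank <- decompose_trials(ts, n_imfs = 3)
  set.seed(5)
  art <- synthesize_trial(bank, 2L)
  set.seed(5)
  donors <- sample.int(6, 3)  # same draw the implementation makes
  oracle <- matrix(0, 3, 128)
  for (k in 1:3) oracle <- oracle + t(bank$class2$stacks[[donors[k]]][k, , ])
  expect_equal(art, oracle, tolerance = 1e-12)
})

test_that("augment_trials obeys the counting law and provenance ordering", {
  ts <- random_trial_set(n_per_class = 5, n_channels = 3, n_samples = 96,
                         seed = 31)
  # multiple 0: unchanged originals
  a0 <- augment_trials(ts, 0, seed = 1)
  expect_identical(a0$trials, ts$trials)
  expect_identical(a0$labels, ts$labels)

  bank <- decompose_trials(ts, n_imfs = 3)
  a3 <- augment_trials(ts, 3, n_imfs = 3, seed = 1, bank = bank)
  expect_length(a3$trials, 40)                       # 2 * (5 + 15)
  expect_identical(sum(a3$provenance == "artificial"), 30L)
  for (y in 1:2) {
    expect_identical(sum(a3$labels == y & a3$provenance == "artificial"), 15L)
  }
  # real trials precede artificial ones
  expect_identical(a3$provenance[seq_along(ts$trials)],
                   rep("real", length(ts$trials)))
  # artificial trials share the real trials' shape
  expect_identical(dim(a3$trials[[40]]), dim(ts$trials[[1]]))
  expect_error(augment_trials(ts, -1), "non-negative")
})

test_that("augmentation is a pure function of trials and seed", {
  ts <- random_trial_set(n_per_class = 3, n_channels = 3, n_samples = 96,
                         seed = 41)
  bank <- decompose_trials(ts, n_imfs = 3)
  a1 <- augment_trials(ts, 2, n_imfs = 3, seed = 99, bank = bank)
  a2 <- augment_trials(ts, 2, n_imfs = 3, seed = 99, bank = bank)
  expect_identical(a1$trials, a2$trials)
  a3 <- augment_trials(ts, 2, n_imfs = 3, seed = 100, bank = bank)
  expect_false(identical(a1$trials, a3$trials))
})

test_that("build_collections yields one collection per multiple", {
  ts <- random_trial_set(n_per_class = 2, n_channels = 2, n_samples = 96,
                         seed = 51)
  coll <- build_collections(ts, multiples = 0:10, n_imfs = 3, seed = 1)
  expect_length(coll, 11)
  sizes <- vapply(coll, function(x) length(x$trials), 1L)
  expect_identical(unname(sizes), as.integer(4 + 0:10 * 4))  # +2*n_real per step
  expect_identical(coll[["m0"]]$trials, ts$trials)

  single <- build_collections(ts, multiples = 0)
  expect_length(single, 1)
  expect_identical(single[["m0"]]$trials, ts$trials)
  expect_error(build_collections(ts, multiples = integer(0)))
})

test_that("artificial trials stay inside the source spectral band", {
  # tonal inputs: IMF mixing cannot create new frequencies
  fs <- 128
  ts <- tonal_trial_set(c(10, 14, 12, 16), n_channels = 2, fs = fs)
  centroid <- function(x) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    half <- seq_len(floor(length(x) / 2))
    sum(f[half] * sp[half]) / sum(sp[half])
  }
  src_c <- vapply(which(ts$labels == 1L),
                  function(i) centroid(ts$trials[[i]][1, ]), 1)
  aug <- augment_trials(ts, 4, seed = 3)
  art_idx <- which(aug$provenance == "artificial" & aug$labels == 1L)
  art_c <- vapply(art_idx, function(i) centroid(aug$trials[[i]][1, ]), 1)
  lo <- min(src_c) * 0.9
  hi <- max(src_c) * 1.1
  expect_true(all(art_c >= lo & art_c <= hi))
})

test_that("within-class mixing only: donors carry the artificial trial's label", {
  ts <- tonal_trial_set(c(8, 20, 8, 20), n_channels = 2)  # class1 = 8 Hz only
  aug <- augment_trials(ts, 2, seed = 7)
  centroid_band <- function(x, fs = 128) {
    sp <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * fs / length(x)
    half <- seq_len(floor(length(x) / 2))
    sum(f[half] * sp[half]) / sum(sp[half])
  }
  for (i in which(aug$provenance == "artificial")) {
    fc <- centroid_band(aug$trials[[i]][1, ])
    if (aug$labels[i] == 1L) expect_lt(fc, 14) else expect_gt(fc, 14)
  }
})
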