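test_that("find_extrema handles monotonic, oscillatory and plateau signals", {
  # monotonic ramp: no interior extrema
  ext <- find_extrema(seq_len(100) / 10)
  expect_identical(ext$maxima, integer(0))
  expect_identical(ext$minima, integer(0))

  # two full sine periods: 2 maxima, 2 minima, increasing order, disjoint
  x <- tone(1, seconds = 2, fs = 250)
  ext <- find_extrema(x)
  expect_length(ext$maxima, 2)
  expect_length(ext$minima, 2)
  expect_true(all(diff(ext$maxima) > 0))
  expect_length(intersect(ext$maxima, ext$minima), 0)

  # 3-sample plateau at the peak: one maximum at the plateau midpoint,
  # oracle = exhaustive neighborhood comparison on the run-compressed signal
  x <- c(0, 1, 2, 3, 3, 3, 2, 1, 0)
  ext <- find_extrema(x)
  expect_identical(ext$maxima, 5L)  # plateau spans 4:6, midpoint 5
  expect_identical(ext$minima, integer(0))

  # even-length plateau: tie broken to the left
  x <- c(0, 2, 2, 0, 3, 0)
  ext <- find_extrema(x)
  expect_identical(ext$maxima, c(2L, 5L))
  expect_identical(ext$minima, 4L)
})

test_that("envelopes bound the signal and track slow amplitude modulation", {
  fs <- 250
  x <- tone(10, seconds = 2, fs = fs)
  ext <- find_extrema(x)
  env <- compute_envelopes(x, ext$maxima, ext$minima)
  ctr <- seq(round(0.25 * length(x)), round(0.75 * length(x)))
  expect_true(all(abs(env$upper[ctr] - 1) < 0.02))
  expect_true(all(abs(env$lower[ctr] + 1) < 0.02))
  expect_true(all(env$upper[ext$maxima] >= x[ext$maxima] - 1e-10))
  expect_true(all(env$lower[ext$minima] <= x[ext$minima] + 1e-10))

  # amplitude-modulated tone: upper envelope tracks a(t) within 5% centrally
  t <- seq(0, 2, by = 1 / fs)
  a <- 1 + 0.5 * sin(2 * pi * 0.5 * t)
  x <- a * sin(2 * pi * 10 * t)
  env <- compute_envelopes(x)
  half <- seq(round(0.25 * length(x)), round(0.75 * length(x)))
  expect_true(max(abs(env$upper[half] - a[half]) / a[half]) < 0.05)

  # two-extrema-only signal: envelope equals the natural spline through the
  # mirrored boundary extrema (direct spline evaluation oracle)
  x <- c(0, 1, 0, -1, 0, 1, 0, -1, 0)
  ext <- find_extrema(x)
  expect_length(ext$maxima, 2)
  env <- compute_envelopes(x, ext$maxima, ext$minima)
  n <- length(x)
  ys <- x[ext$maxima]
  pts_x <- c(2 - ext$maxima[1:2], ext$maxima, 2 * n - ext$maxima[2:1])
  pts_y <- c(ys[1:2], ys, ys[2:1])
  ord <- order(pts_x)
  oracle <- stats::splinefun(pts_x[ord], pts_y[ord], method = "natural")
  expect_equal(env$upper, oracle(seq_len(n)), tolerance = 1e-12)

  expect_error(compute_envelopes(seq_len(10) + 0), "too few extrema")
})

test_that("one sifting step subtracts the envelope mean", {
  fs <- 250
  x <- tone(10, seconds = 2, fs = fs)
  st <- sift_once(new_sifting_state(x + 3))
  ctr <- seq(round(0.2 * length(x)), round(0.8 * length(x)))
  expect_equal(st$iteration, 1L)
  expect_true(max(abs(st$local_mean[ctr] - 3)) < 0.05)       # offset removal
  expect_true(max(abs(st$candidate[ctr] - x[ctr])) < 0.05)
  expect_equal(st$candidate, (x + 3) - st$local_mean)

  # mixture: candidate's spectral peak is at the fast component
  mix <- tone(10) + tone(1)
  st <- sift_once(new_sifting_state(mix))
  sp <- Mod(fft(st$candidate))[2:200]
  freqs <- (seq_along(st$candidate) - 1)[2:200] / (length(mix) / 250)
  expect_equal(freqs[which.max(sp)], 10, tolerance = 0.3)
})

test_that("is_imf accepts canonical IMFs and rejects offset or constant signals", {
  expect_true(is_imf(tone(10)))
  expect_false(is_imf(rep(2, 100)))
  # large DC offset: zero-crossings vanish while extrema remain
  expect_false(is_imf(tone(10) + 10))
})

test_that("decomposition stops on monotonic input and isolates single tones", {
  ramp <- seq(0, 1, length.out = 100)
  d <- emd(ramp)
  expect_length(d$imfs, 0)
  expect_equal(d$residue, ramp)

  x <- tone(10)
  d <- emd(x)
  ctr <- seq(round(0.1 * length(x)), round(0.9 * length(x)))
  expect_true(cor(d$imfs[[1]][ctr], x[ctr]) > 0.99)
  expect_true(sd(emd_reconstruct(d) - x) < 1e-12)
  expect_error(emd(c(1, NA, 3, 4)), "non-finite")
})

test_that("a two-tone mixture separates into its components", {
  t <- seq(0, 2, by = 1 / 250)
  hi <- sin(2 * pi * 10 * t)
  lo <- 0.5 * sin(2 * pi * 1 * t)
  d <- emd(hi + lo)
  ctr <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  expect_true(cor(d$imfs[[1]][ctr], hi[ctr]) > 0.95)
  later <- vapply(d$imfs[-1], function(im) abs(cor(im[ctr], lo[ctr])), 1)
  expect_true(max(c(later, abs(cor(d$residue[ctr], lo[ctr])))) > 0.95)
})

test_that("reconstruction is exact and truncation is accounted for", {
  set.seed(99)
  x <- rnorm(500)
  d <- emd(x)
  expect_true(length(d$imfs) >= 3)
  expect_true(max(abs(emd_reconstruct(d) - x)) / max(abs(x)) < 1e-10)

  # identity on an empty decomposition
  empty <- structure(list(imfs = list(), residue = x, source_length = 500L),
                     class = "imf_set")
  expect_equal(emd_reconstruct(empty), x)

  # dropping terms loses exactly the dropped terms
  keep <- d$imfs[seq_len(min(2, length(d$imfs)))]
  dropped <- Reduce(`+`, d$imfs[-seq_len(min(2, length(d$imfs)))], d$residue)
  trunc <- structure(list(imfs = keep, residue = rep(0, 500),
                          source_length = 500L), class = "imf_set")
  expect_equal(x - emd_reconstruct(trunc), dropped, tolerance = 1e-12)

  bad <- structure(list(imfs = list(rnorm(10)), residue = x,
                        source_length = 500L), class = "imf_set")
  expect_error(emd_reconstruct(bad), "length")
})

test_that("EMD invariants hold over random signals", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(300)
    d <- emd(x)
    # exactness
    expect_true(max(abs(emd_reconstruct(d) - x)) / max(abs(x)) < 1e-8)
    # IMF extrema / zero-crossing condition
    for (im in d$imfs) {
      ext <- find_extrema(im)
      n_ext <- length(ext$maxima) + length(ext$minima)
      s_ <- sign(im)
      s_ <- s_[s_ != 0]
      n_zc <- sum(diff(s_) != 0)
      expect_lte(abs(n_ext - n_zc), 1)
    }
    # determinism
    expect_identical(d$imfs, emd(x)$imfs)
  }
})

test_that("IMFs are ordered from high to low frequency on tonal mixtures", {
  t <- seq(0, 2, by = 1 / 250)
  x <- sin(2 * pi * 20 * t) + sin(2 * pi * 5 * t) + 0.8 * sin(2 * pi * 1 * t)
  d <- emd(x)
  rates <- vapply(d$imfs, zero_crossing_rate, 1)
  expect_true(all(diff(rates) <= 1e-9))
})
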