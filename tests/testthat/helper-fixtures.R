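# shared fixtures, all generated in code

tone <- function(freq, seconds = 2, fs = 250, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, seconds, by = 1 / fs) + phase)
}

# small labeled trial set of band-limited noise trials
random_trial_set <- function(n_per_class = 3, n_channels = 4, n_samples = 128,
                             fs = 128, seed = 1) {
  set.seed(seed)
  labels <- rep(c(1L, 2L), n_per_class)
  trials <- lapply(labels, function(y) {
    matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
  })
  trial_set(trials, labels = labels, sampling_rate = fs)
}

random_spd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d, d)
  crossprod(A) + diag(d) * 0.1
}

zero_crossing_rate <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0) / length(x)
}
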