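---
title: "Reducing BCI calibration time with aligned empirical-mode augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing BCI calibration time with aligned empirical-mode augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaemd)
```

## The problem

A motor-imagery (MI) brain–computer interface decodes which limb movement a
user is imagining from multichannel EEG. The discriminative signature is
event-related desynchronization (ERD): imagery attenuates the power of the
μ (8–13 Hz) and β (14–30 Hz) rhythms over sensorimotor cortex, laterally
organized so that, e.g., left-hand imagery suppresses contralateral rhythms.
Because EEG statistics vary strongly across subjects and sessions, the
classifier must be recalibrated at each use, and collecting enough labeled
trials takes tens of minutes. This package implements and evaluates a
data-augmentation strategy that shrinks that calibration set: synthesize
artificial trials from the few real ones available.

## The method

Three stages, applied in a fixed order (band-pass filter → epoch → select
channels → align → decompose/augment → spatial filter → classify):

1. **Euclidean alignment (EA).** With trials $X_i \in
   \mathbb{R}^{N_C \times N_S}$, the reference covariance is $\bar R =
   \frac{1}{I}\sum_i X_i X_i^T$ and every trial is whitened as $\tilde X_i =
   \bar R^{-1/2} X_i$. Afterwards the mean covariance of the set is the
   identity, so training and test sessions — and, crucially, the real trials
   an artificial trial is built from — share a common reference. EA is
   unsupervised; labels are untouched.

2. **Empirical mode decomposition (EMD) and recombination.** Each channel of
   each training trial is decomposed by iterative sifting into intrinsic
   mode functions (IMFs), ordered from high to low frequency, plus a
   residue; the decomposition is exact by construction. An artificial trial
   of class $y$ is built by drawing an ordered selection of donor trials of
   the same class and summing, per channel, the $k$-th IMF of the $k$-th
   donor. The *multiple* parameter sets how many artificial trials are
   created per real trial (0–10 in the reference protocol, giving 11
   training collections).

3. **CSP + LDA / logistic regression.** Common spatial patterns jointly
   diagonalize the two class covariances; the feature vector is the log
   filtered variance through the $m$ largest- and $m$ smallest-eigenvalue
   filters ($2m$ features, $m = 3$ by default). Classification is
   closed-form LDA ($a = C^{-1}(m_1 - m_2)$, $b = -\frac{1}{2}(m_1+m_2)a$)
   or a Newton-fitted logistic regression; a positive score assigns
   class 1.

The three evaluated pipelines are **baseline** (real trials only), **EMD**
(augmentation on raw trials) and **EA-EMD** (augmentation on aligned
trials). Artificial trials enter the CSP covariances and the classifier
exactly like real ones.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| band | 8–30 Hz | Butterworth band-pass (order 5, zero-phase) covering μ + β |
| epoch window | dataset-specific, e.g. (2.5, 4.5) s | half-open, seconds from trial start |
| channels | 15 central (3×5 grid around C3/Cz/C4) | sensorimotor focus |
| `n_imfs` | 5 | leading IMFs used for synthesis; later IMFs and the residue are discarded |
| `multiple` | swept 0–10 | artificial : real ratio per class |
| `csp_m` | 3 | CSP filter pairs, 6 features |
| `l2_penalty` | 1e-6 | ridge safeguard so separable small samples cannot diverge |
| sifting stop | SD < 0.2, cap 100 | Cauchy-type criterion plus IMF count check |

## Design choices

Several points are genuinely open in the method definition; the package
fixes them as follows.

* **Envelopes and boundaries.** Natural cubic splines through the extrema,
  with the two extrema nearest each boundary mirrored across it before
  fitting — the standard way to suppress spline end swings. Plateaus of
  equal samples count as a single extremum at the run midpoint (ties to the
  left), which makes extrema detection deterministic.
* **Sifting stop.** A candidate is accepted as an IMF when the Cauchy
  criterion $SD = \sum(h_{prev}-h)^2 / \sum h_{prev}^2 < 0.2$ *and* the
  extrema/zero-crossing count condition holds, with a hard cap of 100
  sifting iterations. The residue is always computed as the signal minus
  the running IMF sum, so reconstruction is exact regardless of stopping.
* **Donor selection.** Each artificial trial draws `n_imfs` *distinct*
  donor trials (without replacement) when the class has at least `n_imfs`
  members, with replacement otherwise; the $k$-th donor contributes its
  $k$-th IMF. One donor assignment is shared by all channels, preserving
  the spatial coherence of each IMF layer. Duplicate artificial trials are
  allowed — rejection would bias exactly the small-sample cases the method
  targets.
* **Alignment references.** Training and test sets are each aligned with
  their own reference (EA is unsupervised, so this is legitimate at test
  time); `align_trials(test, reference = ref_train)` gives the shared-
  reference variant.
* **LDA covariance.** The "mean covariance of the two-class features" is
  read as the pooled within-class covariance (classical LDA); the total
  covariance is available via `pooled = FALSE`. A diagonal shrinkage of
  `1e-6 * trace/d` keeps it invertible at 5 trials per class.
* **Best-multiple selection.** The replication convention picks the
  multiple with the highest *test* accuracy ("oracle"), which is
  optimistically biased; `multiple_selection = "cv"` chooses on an inner
  split of the training data and is the honest option for real use.
* **Ties.** A classification score of exactly zero goes to class 2, and
  CSP filter signs are fixed by making the largest-magnitude coefficient
  positive, so all outputs are deterministic.

## The synthetic generator

Real competition recordings require external downloads, so every test in
the package runs on a seeded generator with known ground truth
(`make_subject()`, `generate_session()`):

* band-limited stochastic sources (filtered Gaussian noise, not pure
  sinusoids, so EMD produces several nontrivial IMFs per channel): one
  discriminative μ-band source whose variance is attenuated by the ERD
  depth $d$ for class 2 (power $p$ vs $p(1-d)$), one neutral β source, and
  class-neutral sources at random bands;
* a random orthonormal mixing over 15 channels at 250 Hz, 2-s epochs;
* 1/f sensor noise at a configured SNR;
* a train/test covariance shift $P = I + \text{magnitude}\cdot D$ applied
  to the test session — exactly the linear sensor-space distortion class
  EA corrects; default magnitude 0.3.

The generator emulates band-power class structure, spatial mixing and
session nonstationarity. It does **not** emulate artifacts (EOG/EMG),
non-Gaussian outlier trials, trial-to-trial ERD latency variation, or
volume-conduction physics; passing tests therefore demonstrate the
pipeline's correctness and its behavior under controlled covariance shift,
not performance on any particular real dataset.

With ERD depth 0 the two classes are identically distributed, which gives a
null model: the full EA-EMD pipeline must score at chance level, confirming
augmentation cannot manufacture spurious discrimination.

## Problem sizes and numerical notes

The shipped study (`simulate_study()`, also run by
`scripts/acceptance.R`) uses 20 synthetic subjects, 5 training trials per
class, 50 test trials per class, multiples 0–10 and LDA — large enough for
a stable paired t-test across subjects while keeping a full run in a few
minutes on one core. The null model is evaluated at a fixed multiple of 5
rather than the oracle multiple, since maximizing over 11 noisy accuracy
estimates would bias a chance-level method above 0.5.

Eigen-solves use symmetric eigendecompositions with relative floors
(`1e-10` of the largest eigenvalue) so few-trial references and
near-singular composite covariances fail loudly rather than silently;
degenerate inputs (all-zero trials, one-class sets, bands at the Nyquist
frequency) are rejected with informative errors.

## Limitations

* EMD has no analytic characterization; envelope interpolation and
  boundary rules differ between implementations, so IMFs are
  implementation-defined away from the guaranteed invariants (exact
  reconstruction, count condition, frequency ordering).
* The oracle best-multiple protocol overstates attainable accuracy; use
  the cv mode for honest estimates.
* Only two-class problems are supported, matching the method's scope.
* Loaders for the GDF / MATLAB competition formats are not included; any
  epoched recording can be brought in through `trial_set()` or the
  plain-text exchange format.
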