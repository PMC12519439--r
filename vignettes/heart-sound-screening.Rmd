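---
title: "Heart-sound screening with stethkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound screening with stethkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

A healthy heartbeat is heard as two transients per cardiac cycle: S1
("lub"), which opens systole, and S2 ("dub"), which opens diastole.
Murmurs are additional sounds between them, produced by turbulent flow
through the valves, and their timing and intensity envelope carry
diagnostic information. The taxonomy this package classifies is the one a
clinician applies at first auscultation:

* **normal** vs **murmur** (stage 1);
* murmurs into **systolic** (between S1 and the following S2) vs
  **diastolic** (between S2 and the next S1) (stage 2);
* systolic murmurs into **ejection-systolic (ESM)** — a
  crescendo–decrescendo, "diamond"-shaped intensity — vs **pansystolic
  (PSM)** — constant, "rectangular" intensity (stage 3).

Diastolic murmurs are not subdivided: they are almost always pathologic,
so the screening decision is already made once one is detected. Deeper
diagnoses (valve identification, severity) require ECG or imaging and are
out of scope.

`stethkit` implements the full pipeline around that taxonomy: synthetic
clip generation, preprocessing, linear predictive coding (LPC),
feature extraction, Gaussian-mixture augmentation, four small
convolutional/recurrent network families, the three-stage cascade,
Shapley-value attribution and evaluation statistics.

## The synthetic phonocardiogram generator

Real screening corpora are recorded and expert-annotated; this package
replaces them with a generator so that every result is reproducible from
code. A clip is built as:

* **S1/S2**: Gaussian-windowed tone bursts, one each per cycle, S1 before
  S2. Defaults: S1 at 30–45 Hz for 70–100 ms, S2 at 50–70 Hz for
  50–80 ms, matching textbook phonocardiogram spectra. Systole occupies a
  configurable fraction (default 0.30–0.40) of the cycle.
* **Murmurs**: band-limited (120–400 Hz) Gaussian noise shaped by a
  unit-peak envelope. ESM uses a triangular "diamond" that rises
  monotonically to a single interior peak and falls back to zero; PSM is
  constant at 1 (optionally with short linear ramps); the diastolic
  default is an early-diastolic decrescendo (`exp(-4t)`), since only the
  timing — at/after S2, at/before the next S1 — is clinically definitional
  for that class. Systolic murmur energy is placed strictly inside the
  S1→S2 interval.
* **Noise**: additive white Gaussian noise (default SD 0.02–0.08 relative
  to full scale) with an optional 0.25 Hz amplitude modulation imitating
  breathing (off by default).

The generator records its ground-truth event windows on every clip, so
tests can verify the timing rules against the generator's own log rather
than against heuristics.

**What this does and does not show.** The generator reproduces the
statistical structure the classifier relies on — quasi-periodicity,
murmur timing and envelope shape, spectral separation between valve
transients and murmur noise. It does not model hemodynamics, recording
devices, body-habitus filtering, pediatric/adult spectral differences, or
real ambient noise. A cascade that recovers the taxonomy here has learned
the intended acoustic cues; that is evidence the pipeline works, not that
it reaches any particular accuracy on clinical recordings.

## Preprocessing

Recordings are resampled to 4 kHz (polyphase, anti-aliased), cut to
exactly 3 s — long inputs truncated to their first 3 s, short inputs tiled
end-to-end and then truncated, so every model input is 12,000 samples —
and peak-normalized for gain invariance. Verification gates
non-heartbeat input: the Shannon-energy envelope of the 25–150 Hz band
(20 ms frames) must be periodic inside 40–180 beats/min (autocorrelation
peak) and correlate with a stored reference lub-dub envelope; both scores
must reach the threshold (default 0.6). The check is scale-invariant and
reports "silence" rather than erroring on all-zero input. Whether a
failed check blocks classification or merely flags the result is a
configuration choice (`on_verify_fail`), since in deployment the user is
simply asked to re-record.

## Linear predictive coding

Each 120 ms Hamming-windowed frame (50% hop; 49 frames per clip) is
modelled as an order-12 linear predictor fitted by the Levinson–Durbin
recursion on the frame's raw autocorrelation. Order 12 follows the usual
rate/1000 + extra rule at 4 kHz; 120 ms frames are long enough to contain
an S1 transient. The per-frame coefficients and prediction gain —
49 × 13 = 637 values per clip versus 12,000 raw samples — form the "audio
vector" consumed by augmentation and the classifiers, ordered frame by
frame. The recursion is tested against a direct Toeplitz solve to 1e-8
across orders up to 16; reflection coefficients satisfy |k| < 1 on
positive-energy frames, and silent frames fall back to the trivial
predictor with zero gain rather than erroring mid-clip.

## Named audio features

The explanation path uses a fixed 19-feature space: 13 MFCCs (26-filter
mel filterbank on the power spectrum, log, orthonormal DCT), a scalar
chroma summary (mean of the 12 max-normalized pitch-class energies),
spectral centroid, bandwidth and 85% rolloff from the magnitude
spectrum, per-frame RMS and zero-crossing rate; per-clip vectors are the
frame means. The STFT uses 25 ms Hann frames, 10 ms hop and a 512-point
FFT. Thirteen MFCCs is the community default and covers every index the
attribution analysis names; frame-mean pooling was chosen (and recorded
in configuration) because the attribution plots show one value per named
feature.

## Gaussian-mixture augmentation

Small labelled corpora are grown by fitting one diagonal-covariance
Gaussian mixture per class (default K = 3, EM with a 1e-6 variance
floor, seeded k-means initialization) and sampling each class up to an
explicit allocation. Counting, not sampling, fixes the output sizes, so
allocations are met exactly and originals are retained and tagged
`real` vs `synthetic`. The default allocations grow a 480-clip source
corpus (351 normal / 129 murmur) to 10,000 vectors with 3,600 murmurs of
which 730 systolic, and separately boost the systolic class to 5,000
(ESM/PSM split 2,500/2,500, a package choice — the split is not
specified by the counts above). Note these allocation defaults are
deliberately taken as printed even though 3,600/10,000 does not equal the
source murmur fraction 129/480; the package treats the allocation as
explicit configuration and does not attempt to reconcile the two.
Augmentation operates in the flattened LPC space by default and works
identically in the 19-feature space.

## Network families and training

Four small two-class families over fixed-length sequences:

| Family | Architecture |
|---|---|
| CNN_LSTM | conv(9 filters) → BN → conv(64) → BN → conv(32) → BN → LSTM(8, sequences) → LSTM(4, 20% dropout) → dense → softmax(2) |
| BiLSTM | BiLSTM(128) → BiLSTM(64) → dense(64, ReLU) → dense(32, ReLU) → softmax(2) |
| CNN | conv(9) → BN → conv(64) → BN → conv(32) → BN → global average pool → softmax(2) |
| BiGRU | as BiLSTM with GRU cells |

Design notes on genuinely open points:

* **9/64/32 are filter counts, kernel size is 9.** The two readings
  (filter counts vs kernel sizes) conflict in the source material; filter
  counts are the natural reading of the architecture table, and both are
  configurable.
* **Same-padding convolutions.** Valid convolutions would underflow the
  19-step feature-vector input after three kernel-9 layers; zero-padded
  same-convolutions keep every family applicable to both input modes.
* **CNN head.** The CNN family needs a reduction before softmax; global
  average pooling over time is the standard minimal choice.
* **Optimizer defaults** (unstated upstream): Adam at 1e-3, batch 32, up
  to 100 epochs, early stopping with patience 10 on the loss of a 15%
  validation slice carved (stratified) from the training partition.
* The engine is implemented in R with exact backpropagation through all
  layers; analytic gradients are verified against central finite
  differences in the test suite, which is the strongest practical
  correctness check for a hand-written training engine.

Training uses a stratified 70–30 train/test split under the config seed
(per-class floor on the train side), per-dimension standardization fitted
on the training partition, and returns the held-out indices so
evaluation never touches fitted rows.

## The cascade

Stage 1 sees every clip (normal vs murmur), stage 2 only murmurs
(systolic vs diastolic), stage 3 only systolic murmurs (ESM vs PSM).
Routing is by argmax on hard labels — cascading probabilities between
stages is an alternative that the package deliberately does not use,
keeping each stage's training distribution aligned with what it sees at
inference. Ties vote toward the pathological branch (murmur, systolic),
because the screening cost of missing a murmur dominates the cost of a
false alarm; no probability thresholds beyond argmax are applied by
default, though they are exposed in configuration.

## Explanation

The stage networks consume LPC sequences, but clinical interpretability
calls for named features. The package therefore trains a surrogate of
the same family on the 19-feature vectors and explains it with a
kernel-style Shapley estimator: coalitions of "present" features (absent
ones imputed from a background set, default 100 training vectors) are
evaluated and combined by weighted least squares under the additivity
constraint, so base value plus attributions reconstructs the model
output exactly for every explained sample (10 test cases by default).
When the coalition space is small (≤ 2,046 coalitions) it is enumerated
and the estimate is exact — in particular, linear models receive their
closed-form attributions `w_i (x_i − E[b_i])`; otherwise complete
coalition sizes are enumerated in decreasing kernel-weight order and the
remainder sampled under the seed.

## Evaluation statistics

Accuracy, precision, recall, F1 = 2PR/(P+R) and trapezoidal-rule ROC-AUC
are computed from held-out predictions, with the 2×2 confusion matrix
(rows = true). The accuracy confidence interval uses the normal
approximation `acc ± z·sqrt(acc(1−acc)/n)` clipped to [0, 1]; this
choice reproduces the reference lower endpoint 0.910 at accuracy 0.92
and n = 3,000 to three decimals (upper endpoints agree within 0.002),
which is why it is the default; a seeded bootstrap would be the
alternative when per-sample outcomes are available. Significance against
chance uses the exact one-sided binomial tail P(X ≥ correct | n, 1/2),
computed in log space so p-values far below double precision remain
reportable via `log10_p`. One reference row ("accuracy statistic",
0.851/0.904/0.635) has no stated definition and is deliberately not
implemented as a named quantity.

## Numerical choices and degenerate inputs

* EM variance floor 1e-6 (warned when active); k-means init with 5
  restarts under the seed; EM stops at |Δ log-likelihood| < 1e-8 or 200
  iterations.
* Levinson–Durbin errors on |k| ≥ 1 with the frame index; silent frames
  encode as the trivial predictor.
* All randomness flows through explicit seeds (corpus, per-clip, GMM,
  training, explanation); identical configurations reproduce metrics
  bit-identically, which the test suite asserts by comparing serialized
  metrics files.
* Standardization divisors are floored at 1e-8; softmax is computed with
  the row-max shift.

## Problem sizes used by the tests

The test suite exercises the study-scale arithmetic exactly (480-clip
source corpus; augmentation to 10,000/5,000; 70–30 partitions of
3,000/1,080/1,500) because those are pure counting operations, and the
learning claims at a deliberately separable scale: cascade recovery uses
400 clips per leaf (1,600 clips, held-out 480) with 30-epoch training,
the per-family overfit checks use 200 short sequences, and determinism
uses a 30-clip corpus. These sizes were chosen as the smallest at which
each property is meaningfully tested; the generator's separability at
those sizes is documented above.

## Limitations

* Synthetic clips are far more separable than clinical recordings; the
  recovered cascade accuracy here is an upper bound of pipeline health,
  not a clinical performance estimate.
* No denoising or segmentation of individual S1/S2 events is attempted.
* The verification reference envelope is itself synthetic (a clean
  72 bpm normal clip); unusual but valid rhythms near the 40/180 bpm
  edges score lower, and strong murmurs can themselves depress the
  lub-dub shape score — which is why the default cascade flags failed
  verification on the result instead of refusing to classify.
* Augmentation models classes as diagonal-covariance mixtures in the
  LPC space; correlations across frames are captured only through the
  mixture components.
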