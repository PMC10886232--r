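---
title: "Methods: automated CTS grading from nerve conduction signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated CTS grading from nerve conduction signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ncsdx)
```

## The problem

Carpal tunnel syndrome (CTS) is a compression mononeuropathy of the median
nerve at the wrist. Electrodiagnosis rests on nerve conduction studies
(NCS): the nerve is stimulated and the evoked response recorded. CTS
lengthens the onset latency and attenuates the amplitude of median-nerve
responses while sparing the ulnar nerve, which therefore serves as a
within-hand reference. `ncsdx` implements two automated classification
pipelines over such recordings:

* **Motor pipeline** — compound motor action potentials (CMAP) from the
  median nerve, 6 ms sweeps of 2400 samples (400 kHz), are converted to
  short-time Fourier transform (STFT) spectrogram images and classified
  control vs. patient by a compact three-block 2-D convolutional network.
* **Sensory pipeline** — sensory nerve action potentials (SNAP) from the
  median *and* ulnar nerves, 6 ms sweeps of 1200 samples (200 kHz), are
  decomposed with a Haar multilevel wavelet pyramid, summarised into a
  135-element feature vector per hand, and graded into three severity
  classes (`non`, `mi`, `ms`) by a bank of classical classifiers.

Clinical NCS datasets of this kind are not openly distributable, so the
package ships a parametric waveform simulator that reproduces the data
*shapes* and the severity structure, making every stage testable end to end.

## Motor pipeline

### Spectrograms

A trace is sliced into non-overlapping frames of 120 samples (20 frames per
2400-sample sweep); each frame is multiplied by a periodic Hann window and
discrete-Fourier transformed, keeping the one-sided spectrum (61 bins). The
squared magnitude is the power spectrogram. For imaging, power is
log-compressed as $10\log_{10}(p + \varepsilon)$ with $\varepsilon =
10^{-12}$ (a floor far below any physiological power, present only to keep
the log finite), clipped to a dB range, min–max scaled to $[0,1]$ and
bilinearly resampled to a fixed $256 \times 256$ grid. Although overlapping
frames are common in STFT practice, 20 equal frames of 120 samples on a
2400-sample sweep force hop = frame length; both are overridable.

Two deliberate numerical choices:

* **One shared dB range per batch.** `spectrogram_images()` clips every
  image to the global min/max of its batch and records the range, so a
  trained model sees deterministically scaled inputs at prediction time
  (the range is replayed for held-out data in `pipeline_motor()`).
* **Degenerate images.** An all-equal power matrix (e.g. an all-zero trace)
  has no usable range; it renders as a constant 0.5 image with a warning
  rather than an error, because one flat-line recording should not abort a
  cohort run.

The rendered image is single-channel. Colour spectrogram plots carry no
extra information for a learned classifier — the colormap is a bijection of
intensity — so the network input is one grayscale channel.

### The convolutional classifier

The network is fixed: three blocks of valid-mode convolution (16, 32, 64
kernels of $4\times4$) each followed by ReLU and max pooling ($3\times3$,
$3\times3$, $2\times2$), then flatten, dropout, a 256-unit ReLU dense
layer, and a single sigmoid output trained with binary cross-entropy,

$$\mathrm{Loss} = -\frac{1}{N}\sum_{i=1}^{N} y_i\log p(y_i) +
(1-y_i)\log(1-p(y_i)).$$

On a 256-pixel input the feature maps are $84\times84\times16$,
$27\times27\times32$ and $12\times12\times64$. Note the third block: with a
$2\times2$ pool the arithmetic gives $12\times12$, not the $8\times8$
sometimes quoted for this architecture (which would require a $3\times3$
pool). The stated layer parameters are implemented as given and the block-3
pool size is configurable, so either reading is reproducible;
`layer_shapes()` reports whatever the configuration implies.

Forward and backward passes are implemented from scratch in C++
(im2col + GEMM through Armadillo) with exact gradients (verified against
finite differences in development). Choices the architecture description
leaves open:

* **Optimizer**: Adam, with plain SGD available. At batch size 3 raw SGD
  needs per-problem step tuning; Adam is robust across the learning rates
  the tuning protocol scans.
* **Defaults**: learning rate 0.005, batch size 3, 30 epochs — the tuned
  operating point; `tune_learning_rate()` reproduces the tuning-curve
  protocol (one seeded run per candidate rate).
* **Dropout**: rate unspecified in the architecture; default 0.5, placed
  between flatten and dense.
* **Input centering**: pixel intensities arrive in $[0,1]$ and are shifted
  internally to $[-0.5, 0.5]$. With strictly non-negative input every
  first-layer weight receives a same-sign gradient per kernel position;
  combined with Adam's per-parameter step this reliably drove the first
  ReLU layer into total die-off at the default learning rate. Centering is
  the standard image-preprocessing remedy and is applied identically at
  training and prediction.
* **Weight init**: He-normal, seeded; all randomness (init, shuffling,
  dropout) derives from `cfg$rng_seed`, so a run is bit-reproducible
  single-threaded.

## Sensory pipeline

### Haar pyramid

One analysis step maps consecutive non-overlapping pairs to

$$a_k = \frac{x_{2k-1} + x_{2k}}{2}, \qquad d_k = \frac{x_{2k-1} - x_{2k}}{2},$$

i.e. pairwise means (low-pass) and half-differences (high-pass). This is
the $1/2$-normalised Haar filter pair, not the $1/\sqrt{2}$ orthonormal
convention of most DWT libraries — which is why it is implemented directly
rather than delegated to a wavelet package. The step is exactly invertible
($x_{2k-1} = a_k + d_k$, $x_{2k} = a_k - d_k$), and `mwd()` recurses on the
approximation: depth 5 for the median trace (sub-bands d1–d5, a5), depth 2
for the ulnar trace (d1, d2, a2).

Odd-length sub-bands (1200 → 600 → 300 → 150 → **75** → 38) are handled by
repeating the last sample before pairing. Repetition adds no artificial
edge energy (the padded pair's detail coefficient is 0) and keeps the
transform deterministic; the padding flag is recorded per level and
`mwd_inverse()` drops the synthetic sample on the way back up.

### Features

Each sub-band is summarised by 15 features in a fixed, documented order:
mean; standard deviation; min; max; RMS; median; skewness; kurtosis; the
5th, 25th, 75th and 95th percentiles; zero-crossing count; mean-crossing
count; Rényi entropy. Nine sub-bands × 15 features = 90 median + 45 ulnar
= 135 per hand, named `{nerve}.{subband}.{feature}`.

Conventions where a definition had to be fixed:

* **Moments**: population (n-denominator) SD, Fisher skewness $g_1$ and
  excess kurtosis $g_2$; both defined as 0 for zero-variance input so
  vectors stay finite on degenerate sub-bands.
* **Percentiles**: linear interpolation between order statistics
  (`quantile()` type 7).
* **Crossing counts**: strict sign changes of the deviation from the level;
  samples exactly at the level inherit the previous non-zero sign, leading
  at-level samples are ignored. A count (not an index list) is used because
  a feature table needs scalars.
* **Rényi entropy**: order $\alpha = 2$ over a 16-bin equal-width histogram
  of the sub-band, natural log: $\frac{1}{1-\alpha}\log\sum_i p_i^\alpha$.
  Order 2 (collision entropy) is the most common non-Shannon choice and has
  the direct check $-\log\sum p_i^2$; 16 bins resolve multimodality at the
  shortest sub-band length (38 samples) without starving the histogram.
  Both are configurable and recorded on the feature table.

### Classifier bank and evaluation

Five models — random forest, gradient boosting, multilayer perceptron,
multinomial logistic regression, K-nearest neighbours — are fitted through
their standard R implementations (`randomForest`, `xgboost`, `nnet`,
`nnet::multinom`, `class::knn`) behind one interface. Feature scaling
(training-set mean/SD) is applied for the scale-sensitive models (MLP, LR,
K-NN). The MLP honours the 100-epoch budget as its optimisation iteration
cap; epoch/minibatch settings are meaningless for trees and K-NN and are
not emulated there, and the loss remains cross-entropy (an RMSE objective
for a classifier MLP would be a curve-fitting reformulation with no
benefit).

Evaluation uses stratified k-fold cross-validation (default k = 5; each
fold is the test set exactly once — the usual reading of the protocol) with
an exhaustive grid search tuned by inner 3-fold CV *on the training portion
only*; a leakage test asserts that corrupting held-out labels cannot change
the selected hyperparameters. Default grids are deliberately small
(`default_grid()`), e.g. trees ∈ {100, 300} × mtry fraction ∈ {0.1, 0.33}
for the forest, K ∈ {3, 5, 7} for K-NN. Reported CV accuracy is the
unweighted mean of fold accuracies.

Metrics come from the confusion matrix with fixed class order
(`non`, `mi`, `ms` / `control`, `patient`): accuracy and support-weighted
precision, recall and F1,

$$P_{WA} = \frac{\sum_i |y_i|\,\mathrm{P}_i}{\sum_i |y_i|},$$

and analogously for recall and F1. For single-label classification the
weighted recall is algebraically identical to accuracy — kept as an
invariant test rather than deduplicated, since both quantities are part of
the reporting surface. A class never predicted gets precision 0 and is
flagged.

## The synthetic cohort generator

`simulate_cohort()` stands in for the clinical cohorts. A trace is a sum of
signed Gaussian lobes (three for the triphasic SNAP, two for the biphasic
CMAP) laid end to end after a flat pre-onset baseline, peak-normalised to
the drawn amplitude, plus white Gaussian baseline noise. Per class, onset
latency and amplitude are drawn from normal distributions whose means
encode the clinical severity pattern — latency increases, amplitude
decreases with severity — and the ulnar trace of every sensory hand is
drawn from the healthy distribution regardless of the hand's label, because
CTS spares the ulnar nerve. Every draw is recorded in a manifest.

Two presets fix the study conditions (`ncs_class_params()`):

* `strong` — class means separated by several within-class SDs (e.g.
  sensory latencies 2.2 / 3.0 / 3.9 ms with SD 0.15 ms; amplitudes 40 / 24
  / 10 µV at ~10% SD). This emulates the curated low-noise training data on
  which the pipelines operate near ceiling, and it is the regime in which
  the recovery tests run.
* `overlap` — means shifted by well under one within-class SD with heavier
  noise, so severity classes genuinely interleave and no classifier should
  reach 100%.

Latency values are chosen in realistic clinical ranges for wrist-stimulated
recordings; amplitudes use the conventional µV (sensory) / mV (motor)
scales. The "noise threshold of 0.8" used by the duplication augmentation
is interpreted as a multiplicative scale on each trace's own standard
deviation: `augment_gaussian()` keeps all originals and appends one
duplicate per record with i.i.d. $\mathcal N(0, (0.8\,\hat\sigma)^2)$ noise
per trace, doubling the table (76 motor hands → 152 rows).

What the generator does **not** emulate: electrode placement and
temperature effects, stimulus artifacts, baseline drift, inter-subject
waveform morphology variation beyond latency/amplitude/noise, or any
biophysical cable-equation dynamics. Passing recovery tests therefore shows
that the pipelines extract and use latency/amplitude/shape information
correctly — not that clinical-grade accuracy would be attained on real
recordings.

## Problem sizes and determinism

The recovery checks run at sizes chosen to exercise the full method while
staying desk-scale: sensory recovery on 150 hands (50 per class, 5-fold RF
CV with grid search), permutation-null calibration on 60 hands over repeated
label shuffles with K-NN, and a CNN smoke run on 40 spectrograms for the
full 30 epochs at batch 3 / learning rate 0.005. Functional CNN tests use a
32-pixel two-block configuration, which exercises identical code paths at a
fraction of the cost. All stochastic steps take explicit integer seeds;
identical seeds reproduce cohorts, fits and reports bit-exactly
(single-threaded).

## Known limitations

* The CNN is CPU-only and trains minutes-scale for hundreds of images; it
  is an exact, dependency-free implementation of this one architecture,
  not a general deep-learning framework.
* The clinical validation cohorts are unavailable, so published
  cohort-level accuracies cannot be reproduced here; the package
  demonstrates correctness by oracle equivalence and simulated recovery
  instead.
* Feature screening (the selection that arrived at the 15-feature set) is
  out of scope; the set is fixed.
* `read_signal_table()` expects the package's own long-form CSV dialect;
  vendor electromyograph formats and resampling are out of scope.
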