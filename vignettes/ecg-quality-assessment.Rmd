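---
title: "Featureless quality assessment of single-lead ECG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Featureless quality assessment of single-lead ECG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsqa)
```

## The problem

Wearable and portable single-lead ECG recorders make long-term monitoring
for intermittent atrial fibrillation (AF) practical, but they record in
uncontrolled conditions: motion artifacts, powerline interference,
baseline wander and electromyographic (EMG) noise corrupt a substantial
fraction of the signal.  Downstream rhythm analysis is only trustworthy on
clean intervals, so the first stage of any such pipeline is a quality
gate: decide, for every 5-s segment, whether it is *high quality* (clean
NSR, AF, or another rhythm) or *low quality* (noise).

Classical quality gates compute hand-crafted signal quality indices (SQIs)
and are known to degrade on AF, whose irregular RR intervals and
fibrillatory baseline can mimic noise.  `ecgsqa` implements a featureless
alternative: each raw 5-s segment is converted into a time-frequency
image — a continuous wavelet transform (CWT) scalogram — and classified by
a convolutional neural network with the classic AlexNet architecture,
fine-tuned for the two-class problem.  The package also implements the
standard four-SQI + SVM baseline and the balanced multi-cycle validation
protocol used to compare the two, plus a synthetic single-lead ECG
generator so that the entire pipeline runs without access to clinical
recordings.

## The scalogram front end

For a segment $x(t)$ the CWT at scale $a$ and shift $b$ is

$$W(a, b) = \frac{1}{\sqrt a}\int x(t)\, \psi^*\!\Big(\frac{t-b}{a}\Big)\,dt ,$$

with the analytic Morlet mother wavelet
$\psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2}$.  Numerically the
integral is discretised at the sampling rate over the segment's support
(no padding: samples outside the window contribute nothing) and evaluated
per scale as a zero-padded FFT convolution, batched over scales.  The unit
tests hold this implementation against direct quadrature of the integral
at a relative error below $10^{-3}$; the residual is dominated by the
truncation of the sampled wavelet at `nSigma = 5` Gaussian standard
deviations.

Choices that matter:

* **Centre frequency** `omega0 = 6` rad/s at unit scale — the conventional
  admissible Morlet parameter with balanced time-frequency spread.  The
  pseudo-frequency of scale $a$ is $\omega_0 / (2\pi a)$.
* **Scale grid**: 48 voices per octave, geometric from the scale whose
  centre frequency is Nyquist up to the largest scale whose *energy
  spread* in time ($\sqrt 2$ Gaussian standard deviations each side,
  `boundSigma`) fits the window.  On a 5-s segment this reaches down to
  about 0.5 Hz.  The boundary rule matters: an earlier stricter rule
  (requiring the full 4-sigma support to fit) cut the rendered band at
  about 1.5 Hz and made baseline wander and motion transients — two of
  the four noise families the gate must catch — nearly invisible in the
  image, which measurably destroyed class separability.
* **Rendering**: the coefficient magnitude is min–max normalised per
  segment (making the image invariant to amplitude gain, consistent with
  operating on raw uncalibrated recordings), bilinearly resized to the
  fixed $227 \times 227$ network geometry with low pseudo-frequencies at
  the bottom rows, and quantised through a 128-colour jet palette, so the
  colour index is a monotone function of normalised magnitude.  An
  all-zero segment renders as a uniform image at the lowest colour.

```{r scalogram, eval = FALSE}
rec <- generateClean(synthConfig(fs = 300, durationS = 5, rhythm = "AF",
                                 heartRateBpm = 80, seed = 7))
seg <- segmentRecord(rec)[[1]]
img <- segmentToImage(seg)      # 227 x 227 x 3 jet scalogram
writeScalogramPng(img, "af_scalogram.png")
```

## The classifier

`alexNetSpec()` describes the network exactly: five convolutional layers
(96 kernels of $11{\times}11{\times}3$ at stride 4; 256 of
$5{\times}5{\times}48$; 384 of $3{\times}3{\times}256$; 384 and 256 of
$3{\times}3{\times}192$), ReLU after every learnable layer, cross-channel
response normalisation after the first two, overlapping $3{\times}3$
stride-2 max pooling, and three fully connected layers (4096, 4096, 2)
with dropout, ending in a two-way softmax.  The kernel depths 48/192/192
of conv2/conv4/conv5 are only consistent with the historical two-group
structure, so those layers use `groups = 2`.  All tensor kernels
(im2col+GEMM convolution, response normalisation, pooling) are compiled
code with analytically derived backward passes, each verified against
central finite differences in the tests.

Training is stochastic gradient descent with momentum 0.9 and learning
rate $10^{-4}$ on the two-class cross-entropy (the canonical loss for a
softmax head).  Epochs, batch size and the freeze policy are exposed in
`trainConfig()`:

* `freeze = "none"` — full fine-tuning by backpropagation through the
  whole network.  At roughly 8 s per image per epoch on one CPU this is
  for small demonstrations.
* `freeze = "conv"` — the convolutional base stays fixed; fc6/fc7/fc8
  train on pool5 activations cached per image.
* `freeze = "features"` — only the two-way fc8 head trains, on cached fc7
  activations.  `fastTrainConfig()` packages this desk-scale mode with a
  learning rate of $10^{-3}$ and 60 epochs, chosen for stable convergence
  of the head across repeated holdout splits (at $10^{-2}$ the
  momentum-SGD iteration oscillated on some splits).

Transfer learning is supported through `buildModel(pretrained = TRUE)`,
which loads backbone weights from a locally stored parameter file and
re-initialises only the two-way head.  No weight file ships with the
package and none can be downloaded at build time, so everything the
package itself demonstrates starts from seeded He-initialised weights;
with a random (untrained) convolutional base, the cached-feature modes
amount to training on fixed random convolutional features.  That is the
main respect in which desk-scale results here understate what the method
achieves with an ImageNet-pretrained backbone.

Input images are standardised per channel with the usual ImageNet
statistics before entering the network; no augmentation is applied.
Prediction returns the two softmax probabilities and a hard label, with an
exact tie (0.5) resolved to LOW — the conservative direction for a quality
gate.

## The SQI + SVM baseline

The comparison method combines four classic indices per segment:

* `bsqi` — agreement of two independent QRS detectors (Pan–Tompkins-style
  and Hamilton–Tompkins-style; bandpass, derivative, rectify or square,
  moving-window integration, adaptive threshold with refractory period),
  as matched fraction of the peak-train union with greedy one-to-one
  matching within 150 ms;
* `psqi` — periodogram power in 5–15 Hz over 5–45 Hz;
* `bassqi` — one minus power in 0–1 Hz over 0–40 Hz;
* `ksqi` — kurtosis, non-excess convention (Gaussian noise scores 3).

The four features are z-scored by training-set statistics (without which a
$\gamma = 1$ Gaussian kernel is meaningless across feature scales) and fed
to an SVM with a radial kernel, $C = 25$, $\gamma = 1$.

## The validation protocol

Class imbalance is handled by repeated balanced cycles
(`canonicalPlans()`): 40 cycles that keep all 1168 low-quality segments
and draw 468 NSR + 340 AF + 330 OR high-quality segments (the PC2017
scope); 19 cycles at 1200 low and 600 NSR + 600 AF (PDB); one cycle on the
already-balanced THDB; and 40 combined cycles drawing 1000/500/1000
segments per class from the three sources with near-equal rhythm mix
inside each quota.  Within a cycle, a stratified 80/20 holdout (stratified
jointly on quality and rhythm; per-stratum test counts rounded, the
largest stratum absorbing the remainder so the global split is exact) is
repeated five times — 500 learning-testing iterations across all scopes.
Each run reports Se, Sp, Acc and the per-rhythm retention rates RNSR, RAF,
ROR; aggregation is mean, sample standard deviation ($n-1$), maximum and
minimum across runs.  Zero-denominator metrics are reported as `NA`, never
silently as zero.  Splits for all runs are drawn before any model fitting,
so two classifiers evaluated with the same seed see identical splits.

High-quality subsets of different cycles may overlap (sampling is
independent per cycle); a window overlapping *any* noisy annotation is
labeled LOW (a window containing expert-flagged noise is not guaranteed
clean), and a clean window spanning two rhythms takes the majority rhythm
with ties resolved toward AF, the clinically critical class.

## The synthetic generator

`generateClean()` builds beats as a sum of Gaussians (P, Q, R, S, T) on a
quasi-periodic R-peak train; NSR uses an RR coefficient of variation of
2%, AF draws RR intervals at CV 24% with the P wave removed and a slowly
amplitude/frequency-modulated ~6 Hz fibrillatory oscillation added, and
"other rhythm" interleaves every third beat with a wide, large, P-less
ectopic beat.  `addNoise()` rescales one of the four noise families —
baseline wander (sum of sinusoids below 0.5 Hz), 50 Hz powerline, EMG
(white noise high-passed at 20 Hz), motion artifacts (3–6 large
low-frequency Gaussian transients) — so the realised whole-window SNR
equals the request exactly.  Ground-truth R-peak times are carried in the
record metadata, and `generateBenchmark()` can write everything as
single-column CSVs plus a manifest so the synthetic path exercises the
real reading code.

What the generator does *not* emulate: real electrode-motion artifacts
that morphologically mimic QRS complexes, pathological morphology
diversity, non-stationary noise mixtures, or inter-patient variability.
Passing the synthetic benchmark therefore demonstrates that the pipeline
is implemented correctly and can learn the clean/noisy distinction from
images alone; it does not certify clinical performance.  Notably, the four
synthetic noise families are precisely the textbook targets of the four
SQIs, so the baseline is close to ceiling on synthetic data — the
advantage of the image-based method on real AF recordings should not be
expected to reproduce here.

## Problem sizes and numerical choices

The desk-scale benchmark used by the tests and the acceptance script is
600 records (300 high-quality split NSR/AF, 300 corrupted at SNR drawn
from $[-6, 0]$ dB across the four noise families) of 5 s at 300 Hz, one
balanced cycle, five holdout repetitions, with the CNN in the fast
frozen-base mode.  One run takes a few minutes on a single CPU.  All
randomness — record content, noise realisations, splits, shuffling,
dropout, head initialisation — derives from one integer seed, and the
pipeline is bit-reproducible under it (the tests regenerate the benchmark
and compare manifests and rendered images byte for byte).

Degenerate inputs are defined, not accidental: an all-zero segment has a
zero transform and renders as a uniform lowest-colour image; a
zero-variance segment has undefined kurtosis (flagged, reported as 0 in
the feature vector); empty peak trains give `bsqi = 0`; a learning rate of
0 provably leaves the network unchanged.

## Known limitations

* No pretrained backbone ships with the package; until one is supplied
  via `options(ecgsqa.alexnet_weights=)`, the convolutional features are
  random projections and desk-scale accuracy understates the method.
* Full fine-tuning on one CPU is impractical beyond toy sizes; the
  compiled kernels are single-threaded by design (BLAS aside).
* The WFDB reader covers the common single-lead format-16 (and
  MAT-stored) case only; the MAT reader covers Level 4 and uncompressed
  Level 5 numeric matrices.
* Quality labels are binary; multi-level grading is out of scope.
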