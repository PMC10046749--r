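---
title: "Detecting mental stress from in-ear PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mental stress from in-ear PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earppg)
```

## The problem

Photoplethysmography (PPG) measures blood-volume changes optically; the AC
component of an in-ear PPG tracks the cardiac pulse, whose rate and pulse
morphology shift under acute mental stress (faster, weaker beats driven by
sympathetic activation). `earppg` implements a complete classification
pipeline from raw two-channel PPG plus tri-axis acceleration to a binary
stressed / non-stressed decision:

1. artifact-aware preprocessing (DC removal, bandpass, channel fusion, RLS
   motion-artifact cancellation),
2. fixed-length segmentation with subject-disjoint train/test splits,
3. generalized-Morse-wavelet scalogram images,
4. a compact CNN trained with binary cross-entropy,
5. confusion-matrix metrics and ROC/AUC.

Wearable stress datasets of this kind are rarely shared, so the package
ships a seeded synthetic generator that reproduces the statistical
structure the pipeline assumes. Every stage is exercised end-to-end on that
generator.

## The synthetic signal model

`generator_config()` fixes the study conditions: 14 subjects, 180 s per
condition per subject, 100 Hz sampling. Each recording is

\[
\mathrm{PPG}(t) \;=\; \mathrm{DC} + p(t) + d(t) +
g_\mathrm{ma}\,\big(w_x a_x(t) + w_y a_y(t) + w_z a_z(t)\big) + \varepsilon(t),
\]

where

* \(p(t)\) is a pulse train: one two-lobe template per beat (a dominant
  systolic peak at 30% of the beat interval, plus a 0.35-amplitude dicrotic
  lobe at 65%), beat intervals \(60/\mathrm{HR}\) seconds with Gaussian
  jitter (`hrv_sd`, default 0.05 s). The non-stressed heart rate defaults
  to 70 bpm; stressed to 95 bpm with pulse amplitude scaled by
  `amp_ratio_stressed` = 0.6 — faster, weaker beats with more closely
  spaced intra-beat peaks, which is the qualitative contrast the classifier
  must learn. The systolic lobe width is 0.11 of the beat interval: wide
  enough that the pulse *fundamental*, not its second harmonic, dominates
  the wavelet ridge (a narrower lobe pushes spectral energy into the
  harmonics and makes the ridge ambiguous).
* \(d(t)\) is baseline wander: a sinusoid with random frequency in
  0.03–0.08 Hz and amplitude `dc_drift_amp` = 2 (pulse units), plus a
  constant sensor offset.
* \(a_{x,y,z}(t)\) are the acceleration channels: scaled copies
  (1 : 0.6 : 0.3) of one shared bursty movement signal (Gaussian-envelope
  oscillations at 1–3 Hz, roughly one burst per 25 s, amplitude 2–4) plus
  smoothed per-axis sensor noise and a constant gravity offset. Sharing one
  movement source across axes is deliberate: it is the regime in which a
  *single-axis* reference can cancel most of the coupled artifact, i.e. the
  generative assumption under which RLS cancellation is well-posed. The
  burst frequencies sit inside the pulse band on purpose, so uncancelled
  artifacts genuinely confuse a classifier.
* \(\varepsilon(t)\) is white noise (`noise_sd` = 0.3 per optical channel,
  independent between channels). The red channel is a 0.6-scaled copy of
  the same pulsatile/artifact source with its own noise, which is what
  makes normalize-and-average fusion meaningful.

The default noise and artifact levels were chosen once so that
classification of raw traces is poor while the cleaned pipeline is strong —
that gap is what makes the preprocessing value observable in tests. What
the generator does **not** model: validated physiological PPG morphology,
respiration or blood-pressure coupling, sensor saturation, or any
particular stressor timing (each condition block is stationary; no
task-onset structure). Passing tests therefore demonstrate that the
pipeline recovers the structure this model encodes, not performance on real
recordings.

Determinism: every recording's RNG stream is derived from
`(seed, subject_id, condition)` via a fixed string hash, so datasets are
bit-reproducible and subjects are stream-separated.

## Preprocessing

`preprocess_recording()` applies, in order (to both optical channels *and*
all three acceleration channels, which are conditioned exactly like the
PPG):

**DC remover.** The first-order IIR structure
\(m(t) = x(t) + a\,m(t-1)\), \(y(t) = m(t) - m(t-1)\), i.e.
\(H(z) = (1 - z^{-1})/(1 - a z^{-1})\). Its zero at \(z = 1\) makes the DC
gain exactly 0 for any \(a < 1\); at \(a = 1\) it reduces to the identity.
The pole parameter is unspecified in most descriptions of this filter, so
`a = 0.95` at 100 Hz is the default (cutoff well below the 0.5 Hz pulse
band); `m(0)` is initialized at the constant-input steady state
\(x(1)/(1-a)\), which removes the start-up ramp that would otherwise
dominate short segments.

**Bandpass.** A 4th-order Chebyshev type-II design with band edges
0.5–3.5 Hz (the human pulse band) and 30 dB stopband attenuation, applied
forward-only (causal), as a streaming device would. Attenuation and the
causal choice are exposed in `preprocess_config()`.

**Fusion.** Infrared and red channels are z-scored and averaged. z-scoring
makes fusion invariant to per-channel gain — consistent with
"normalize and average" — and averaging independent channel noise reduces
its variance.

**Reference selection.** Pearson correlation between the fused PPG and
each cleaned acceleration axis, over the whole recording (one reference per
recording, not per segment). The axis with the largest \(|r|\) is accepted
if \(|r|_{\max} > 0.3\); exact ties fall back to the fixed order x, y, z.
Below threshold, RLS is bypassed entirely — adapting against an
uncorrelated reference only injects noise.

**RLS cancellation.** Exponentially weighted recursive least squares with
forgetting factor \(\lambda = 0.999\), 12 taps, \(P(0) = \delta^{-1} I\)
with \(\delta = 0.01\), \(\omega(0) = 0\). At sample \(n\) the regressor is
the last 12 reference samples, the artifact estimate is
\(N'(n) = \omega^\top(n) N(n)\), and the cleaned output is the a-priori
error \(X'(n) = d(n) - N'(n)\). With \(\lambda = 1\) the recursion is
algebraically identical to ridge-regularized growing-window least squares
(the test suite checks this identity against explicit normal equations, and
checks steady-state residuals against a batch least-squares oracle on
stationary mixtures). \(P\) is re-symmetrized each step against round-off;
a non-finite update aborts with the offending sample index.

## Segmentation and splitting

Cleaned signals are tiled into non-overlapping windows of 3 or 5 s
(half-open sample ranges, 0-based; trailing remainders dropped, so counts
are exact multiples). Splits are made at the *subject* level: with 14
subjects, 180 s per condition, and an 11/3 split, the bookkeeping is

| window | train | test |
|---|---|---|
| 3 s | 11 × 2 × 60 = 1320 | 3 × 2 × 60 = 360 |
| 5 s | 11 × 2 × 36 = 792 | 3 × 2 × 36 = 216 |

Which subjects land in the test set is a seeded shuffle, recorded in the
run artifacts — the assignment itself is not prescribed anywhere, so
reproducibility, not a particular assignment, is the contract.

## Scalograms

The continuous wavelet transform uses the generalized Morse family,
defined in the frequency domain as
\(a_{\beta,\gamma}\,\omega^{\beta} e^{-\omega^{\gamma}}\) on
\(\omega \ge 0\) (analytic). Defaults \(\gamma = 3\), \(\beta = 20\)
(time–bandwidth product 60) are the conventional general-purpose choice.
The peak angular frequency of the mother wavelet is
\((\beta/\gamma)^{1/\gamma}\), giving center frequency
\(F_c = (\beta/\gamma)^{1/\gamma} / 2\pi\) cycles/sample, and scale \(a\)
maps to frequency via \(F = F_c \cdot f_s / a\) — an identity the grid
carries to machine precision.

Scales are geometric, 12 voices per octave, covering 0.4–8 Hz: the pulse
fundamental plus the first harmonics passed by the 0.5–3.5 Hz prefilter.
Each wavelet row is normalized to unit peak; segments are zero-padded to
the next power of two at least twice their length to limit circular
wrap-around; the cone of influence is not masked. Magnitudes are rendered
to fixed-size RGB images (224 px reference size) by separable linear
resampling, per-image min–max normalization, and a pinned perceptual
colormap (`grDevices::hcl.colors(256, "viridis")`, with a grayscale
fallback). Per-image normalization makes renderings invariant to overall
signal amplitude — so the classifier must use time–frequency structure,
not raw energy.

## The classifier

The reference architecture is fixed: 4 blocks of [2 × conv(64 filters,
3×3, ReLU, same padding) → maxpool 2×2 → dropout 0.25], then flatten →
dense 128 (ReLU) → dropout 0.5 → dense 1 (sigmoid), trained with binary
cross-entropy; optimizers Adam, RMSprop, or SGDM (SGD with momentum 0.9),
learning rate 1e-4, batch 32, up to 50 epochs with patience-10 early
stopping on a stratified 20% validation holdout.

A note on strides: applying stride 2 in *every* convolution as well as in
pooling would collapse a 224-px input below one pixel before the fourth
block — the four-block topology is only geometrically possible with
stride-1 convolutions, which is the default here. `build_cnn()` will
happily build stride-2 variants with fewer blocks, and rejects impossible
geometries with a layer-by-layer shape trace.

The implementation is native R: convolutions are im2col index expansions
followed by BLAS matrix products, with hand-written backpropagation and
optimizer states. Max-pool gradients are routed to the first maximal
element in the fixed window order; dropout is "inverted" (scaled at train
time) and disabled at prediction, so prediction is a pure function.
Training, initialization (fan-in-scaled Gaussian), shuffling and dropout
all draw from streams derived from the config seed, so training is
bit-reproducible on a fixed BLAS.

**Augmentation.** Each training image can gain one white-Gaussian-noise
copy (mean = 30% of the image's mean intensity, SD = 10% of its intensity
SD — the SD fraction is a package default, exposed in `augment_config()`),
clipped to [0, 1], doubling 792 training images to 1584. Noise is applied
to training images only.

## Evaluation

`eval_report()` computes the confusion matrix at threshold 0.5 (stressed =
positive), accuracy / precision / recall / F1 in percent (zero-denominator
cases are reported `NA` and flagged, never silently 0), and a ROC by
threshold sweep over unique scores with trapezoidal AUC — which for a step
ROC equals the Mann–Whitney rank statistic with ties counted half; the
test suite holds the implementation to that identity and to `pROC`.

## Desk-scale configuration

The package defaults mirror the reference setup (224-px images, 64
filters, lr 1e-4, up to 50 epochs). End-to-end runs in the test suite and
`scripts/acceptance.R` use a desk-scale configuration chosen once: 32-px
images, 8 filters, RMSprop at lr 1e-3, 10 epochs, full 14-subject data
with 5 s windows. At 32 px the ridge geometry that separates the classes
(a ~1.2 Hz vs ~1.6 Hz ridge row, about 3 rows apart on this grid) is fully
preserved, and a complete pipeline run takes about a minute. The
no-preprocessing ablation feeds scalograms of the raw infrared channel to
the identical classifier.

## Known limitations

* The generator is a statistical stand-in, not a physiological model;
  results on it do not transfer to real in-ear recordings.
* RLS cancels only the artifact component linearly predictable from the
  single selected axis; cross-axis residuals survive by construction
  (small, because the generator couples axes to one movement source).
* The causal Chebyshev-II stage has nonzero group delay; no zero-phase
  (forward–backward) option is provided, matching streaming use.
* Bit-reproducibility of training holds for a fixed BLAS/platform;
  floating-point reduction order may differ across linear-algebra
  libraries.
* The stride-2 "literal" CNN variant is buildable but not part of any
  tested claim.
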