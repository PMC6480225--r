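---
title: "Multi-scale convolutional activity recognition: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale convolutional activity recognition: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarsefine)
```

## The problem and the model

Smartphone inertial sensors deliver six synchronized channels — tri-axial
acceleration (g) and tri-axial angular velocity (rad/s) — from which we
classify six everyday activities. The classification unit is a fixed
window, by default 2.56 s at 50 Hz = 128 samples. Ambulatory activities
(walking, stairs) are quasi-periodic with class-specific cadence and
harmonic content; postural activities (sitting, standing, laying) are
distinguished mostly by the orientation of the gravity vector in the
device frame. A single-resolution convolutional network must choose one
effective temporal receptive-field schedule; the coarse-fine strategy
instead runs three branches in parallel over the same window:

* **fine** — four convolution + max-pool stages, each halving the length:
  small receptive fields early, fine temporal detail;
* **medium** — two stages with stride-2 convolutions and size-4 pools;
* **coarse** — a single stride-2 convolution with a size-16 pool:
  one aggressive summary of the whole window.

Each branch ends in an 8-position × 36-filter map; the three flattened
maps concatenate into an 864-element fused vector feeding dropout, a
128-unit rectified hidden layer and a soft-max. All convolutions use
kernel length 2 and ReLU activations.

### The loss

Every branch carries an auxiliary soft-max classifier on its own
flattened output. Writing Θ₁, Θ₂, Θ₃ for the branch parameter sets and W
for the fused classifier, the per-window loss is

$$\zeta(\Theta_1,\Theta_2,\Theta_3,W)
 = -\sum_{i=1}^{3}\log \hat p(m\mid\Theta_i) \;-\; \log \hat p(m\mid W),$$

averaged over the minibatch (`total_loss()`, head weights configurable).
This is deep supervision: the gradient reaching each branch does not have
to survive the fusion layer, and each branch is pushed to be independently
discriminative. The auxiliary heads are dropped at inference. With head
weights $(0,0,0,1)$ the loss reduces exactly to the fused head's
cross-entropy, which the tests assert.

## Architectural reconciliation

The branch tables we implement deviate from a literal reading of their
source in two places, and the package treats this as a first-class design
decision (`default_config(literal_strides = TRUE)` restores the literal
tables). The published architecture states the fused vector has
864 = 8 × 36 × 3 elements, i.e. every branch emits 8 positions. Only a
same-padding convention reproduces the fine branch's chain
128 → 64 → 32 → 16 → 8, and the literal medium (second conv stride 3) and
coarse (pool stride 2) strides yield 6 and 32 positions respectively —
not 8. The defaults therefore use medium conv strides (2, 2) and coarse
pool stride 8: the minimal edits under which all three branches emit
8 × 36, matching the only cross-checkable anchor of the architecture. The
shape calculus (`branch_output_length()`: same → ⌈L/s⌉, valid →
⌊(L−k)/s⌋+1) is validated against forward passes of built models on
randomized branch specifications.

Two further under-specified points we fixed: the hidden width of the
fully-connected block (not stated; we use 128, between the 864-wide fusion
and the 6 outputs, configurable), and an inconsistency between a stated
dropout rate of 0.00005 and a separately tabulated dropout probability of
0.8 alongside weight decay 0.00005 — we read the table as authoritative:
keep-probability 0.8, weight decay 5e-5.

## Training

`training_config()` defaults mirror the reference setup: learning rate
1e-4, weight decay 5e-5 (applied as an L2 term on weights only, inside the
optimizer step — biases are exempt), momentum 0.5–0.99, minibatch 500, up
to 2000 epochs. The momentum range is given only as an interval; we chose
the simplest reading, a linear per-epoch ramp from 0.5 at epoch 0 to 0.99
at the final epoch (`momentum_at()`), with a constant-momentum mode
available by setting both ends equal. The last incomplete minibatch of an
epoch is used rather than dropped, and each epoch's shuffle (and dropout
masks) are seeded from the master seed, so a (seed, data) pair fully
determines the run in single-threaded execution. Divergence (non-finite
loss) aborts with a diagnostic. There is no early stopping by default.

Weight initialization is seeded He-scaled Gaussian (sd = √(2/fan-in)),
appropriate for rectifier networks. The backward pass is hand-derived;
the test suite compares it against central-difference gradients (step
1e-5) at a 1e-4 relative tolerance on every parameter family — convolution
kernels, biases, auxiliary and fused heads.

### The desk-scale schedule

`quick_training_config()` — learning rate 0.01, batch 64, 60 epochs, same
momentum ramp and decay — is the package's profile for the synthetic
experiments, the test suite and the worked examples. At the synthetic
benchmark's size (600 windows of 128 × 6, 420 SGD steps) it converges to
100% held-out accuracy in under a minute of CPU time; the full-scale
defaults exist for runs on the real benchmark downloads. The higher
learning rate compensates for the much smaller dataset and batch size;
it was fixed when the profile was designed, before it became the standing
benchmark configuration.

## Preprocessing

* **FIR low-pass** (`fir_lowpass()`): Hamming-windowed sinc design
  (`signal::fir1`), default cut-off 10 Hz, 51 taps (odd, so linear phase
  with integer group delay). Neither the order nor the design method of
  the reference filter is published; this is the standard linear-phase
  choice, and both are configurable. Application is zero-phase: reflect
  both ends, convolve with centred taps, crop — output length equals input
  length and pass-band signals are not delayed. The tests verify the
  realized attenuation against the taps' transfer function evaluated
  independently at stop-band and pass-band frequencies.
* **Segmentation** (`segment_stream()`): windows of
  `round(window_seconds × sampling_hz)` samples; default 50% overlap —
  the convention under which the 128-sample benchmark windows were
  produced — trailing partial windows discarded. At WISDM's 20 Hz a
  2.56 s window is 51 samples; the network input length is a
  configuration value, not a constant.
* **Standardization** (`standardize()`): per-channel z-scoring, with
  test-time application of train-time statistics (no leakage; asserted in
  tests). Standardization is not part of the published pipeline; it is on
  by default because it stabilizes SGD, and can be disabled
  (`preprocessing: standardize: false` or `--no-standardize`) for a
  literal-pipeline mode. Zero-variance channels standardize to zero with
  scale kept at 1.
* **Channel selection**: the UCI HAR layout ships nine raw signal groups;
  the model consumes six. The default is total acceleration + body
  gyroscope, matching a literal "tri-axial accelerometer and gyroscope";
  the gravity-removed body-acceleration variant is selectable
  (`channel_set = "body_acc"`) since the published pipeline does not say
  which variant it used.

## The synthetic generator

`generate_dataset()` emulates what makes the real classes separable:
ambulatory classes are harmonic series at class-specific gait frequencies
(walking 2.0 Hz, upstairs 1.6 Hz with a heavier second harmonic,
downstairs 2.4 Hz, jogging 2.8 Hz) with per-window phase and ±15%
amplitude jitter, accelerometer noise σ = 0.05 g, and attenuated
phase-shifted copies on the gyroscope channels; postural classes hold
class-specific gravity orientations at least 45° apart with low noise.
Windows are dealt round-robin to synthetic subjects, so every subject sees
every class and subject-independent splits stay class-balanced. Class
distinctiveness is deliberately strong: the reference result this stands
in for is a 100% recognition rate, so the surrogate must make 100%-level
accuracy reachable — the architecture, not the data, is under test. A
`hard = TRUE` mode narrows the gait frequencies and triples the noise for
ablation work.

What the generator does **not** model: inter-subject gait variability
(synthetic "subjects" are i.i.d. windows), sensor drift and orientation
changes within a window, transitions between activities, label noise, and
class imbalance. Passing the synthetic benchmark therefore demonstrates
that the architecture, loss and optimizer can extract multi-scale
temporal structure end to end — it does not predict accuracy on real
recordings, which is what the full-scale benchmark paths
(`read_uci_har()`, `read_wisdm()`) are for.

## Numerical choices and degenerate inputs

* Same-padding puts the extra sample on the right; max-pooling pads with
  −∞ so padded positions never win; pooling ties break to the earliest
  position (relevant only for gradient routing).
* Soft-max is computed with row-max subtraction; probabilities at the
  true class are clamped at 1e-12 inside the loss (with a warning) so a
  confidently wrong head yields a large finite loss rather than ±Inf.
* Dropout is inverted (mask scaled by 1/keep), so inference needs no
  rescaling.
* Empty datasets, vocabulary mismatches, shape mismatches and
  sub-window-length streams all raise (or warn and return empty) with
  messages naming the offending quantity; malformed WISDM records are
  skipped and counted rather than aborting, because the public file is
  known to contain glitches.
* Evaluation with zero-support classes flags them instead of dividing by
  zero; the mean average accuracy averages supported rows only.

## Problem sizes used by the tests

The standing benchmark experiment uses 100 windows per class (600 total),
a 70/30 subject-independent split over 10 synthetic subjects, and the
desk-scale schedule; the remaining tests use 16–64-sample windows and 2–5
epochs. These sizes are the package's chosen test conditions and keep the
whole suite under a minute on a single CPU core.

## Known limitations

* Pure-R training is practical at desk scale (hundreds of windows) but
  slow for the full 7352-window benchmark at 2000 epochs; the
  implementation is single-threaded-deterministic first, fast second.
* The literal-strides architecture is constructible but its fusion width
  (1656) differs from the published 864; we document rather than resolve
  the discrepancy.
* WISDM streams are 3-channel (accelerometer only); models for them must
  be configured with `input_channels = 3`, and no resampling between
  20 Hz and 50 Hz is provided.
* The momentum schedule within the stated 0.5–0.99 range, the hidden
  width, and the benchmark's windowing of WISDM are all unstated in the
  source material; our choices (linear ramp, 128, 2.56 s at 50% overlap)
  are documented above and configurable.
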