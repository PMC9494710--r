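---
title: "Methods: windowed sEMG features, compact CNN+LSTM classifiers, and flash budgeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed sEMG features, compact CNN+LSTM classifiers, and flash budgeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`emgrec` implements a complete desk-scale pipeline for surface
electromyography (sEMG) gesture recognition aimed at small embedded
controllers: signal conditioning, sliding-window feature construction,
four compact CNN/LSTM hybrid classifiers trained by an in-package engine,
a flash-budget size estimator, and intra/inter-experiment evaluation. A
seeded synthetic generator stands in for subject recordings, so every stage
is reproducible from a single seed. This vignette records the models, the
parameter choices that matter, and the design decisions that were genuinely
open.

## Signal model and preprocessing

Recordings are six channels sampled at 2 kHz. Conditioning follows common
sEMG practice, each stage applied per channel:

1. **High-pass**, third-order Butterworth at 20 Hz, removing motion artifact
   and electrode drift.
2. **Low-pass**, disabled by default. Anti-aliasing in this acquisition
   chain is an analog concern: a digital "low-pass at the sampling rate"
   would sit above Nyquist, where no digital filter exists. If a user
   enables a cutoff at or above `fs/2` the pipeline raises a configuration
   error rather than silently clamping.
3. **Notch** at 50 Hz for power-line interference, realised as the standard
   RBJ biquad with quality factor Q = 30 (centre over −3 dB bandwidth);
   narrow enough that 30 Hz and 70 Hz tones lose under 3 dB.
4. **Min-max scaling** of each channel onto [0, 1] over the whole segment,
   with the original ranges retained for inversion. A constant channel maps
   to 0.5 with a warning rather than dividing by zero.

All filters run forward-backward (`signal::filtfilt`), so the pipeline is
zero-phase: channels stay mutually aligned, at the cost of being an offline
(non-causal) method — real-time filtering is explicitly out of scope. The
quoted attenuation figures in the tests account for the doubled effective
order this implies.

Preprocessing is always applied *after* splitting (see below), so min-max
statistics cannot leak across train/test boundaries.

## Windowing and features

Three windowing scales coexist, all parameters of `window_spec()`:

* **Network-input windows**: 200 samples (100 ms), cut per labelled trial
  segment. The step between windows defaults to 200, i.e. non-overlapping:
  overlapping windows would make adjacent train examples near-duplicates
  and, at split boundaries, near-duplicates across splits. Non-overlap keeps
  each window an independent classification event.
* **FFT frames**: 100 samples at step 100 inside each window — two disjoint
  frames per window, each replaced by its 100-point DFT magnitudes (bin
  resolution 20 Hz). Spectra are kept two-sided so the tensor stays
  200 × 6 × 1 regardless of feature kind.
* **Scalar-feature sub-windows**: 100 samples at step 1, for the five
  classical time-domain descriptors (MAV, WL, SSC, ZC, RMS), giving a
  101-step feature stream per window that is zero-padded to 200.

The ZC and SSC counts are gated by an amplitude threshold `zc_epsilon`
(default 0.01 on the normalized scale) so electrode noise does not register
as crossings; SSC requires both adjacent differences to exceed the
threshold, ZC requires the jump across zero to.

The fused **FFT+RMS** representation rescales each frame's magnitude vector
to unit RMS and multiplies it by the raw frame's time-domain RMS. The
spectral *shape* and the contraction *intensity* are thereby carried in one
vector: the output frame's RMS equals the raw frame's RMS exactly (a
Parseval-style bookkeeping identity the tests check). This fusion is one
concrete reading of an under-specified construction; it is isolated in a
single internal function so alternatives can be swapped without touching
the rest of the pipeline.

Feature tensors persist through an Arrow Parquet table plus a JSON manifest
(feature kind, tensor dimensions, window spec, schema version); the round
trip is bit-lossless and validated on load.

## The four classifiers

All variants consume 200 × 6 × 1 tensors and end in dropout (rate 0.2) →
dense(16) → leaky-ReLU → softmax. A conv block is convolution +
leaky-ReLU + max pool (pool length 1, i.e. identity, by default — pooling
is declared in the design but absent from the reference size arithmetic, so
it defaults off with a config switch).

| variant | feature extractor | recurrence |
|---|---|---|
| `CNN` | conv 40×6, 128 maps (valid) | none (flatten) |
| `CNN_LSTM` | conv 40×6, 128 maps (valid) | LSTM(32) |
| `CNN2D_LSTM` | conv 40×6 → 128 maps (same), conv 20×6 → 8 maps (valid) | LSTM(32) |
| `CNN2D_LSTM2D` | as `CNN2D_LSTM` | LSTM(32, sequence) → LSTM(16) |

In the default `CNN2D_LSTM`, same-padding keeps the first conv at 200 × 6,
and the valid 20×6 second conv yields 181 × 1 × 8; the reshape unit turns
that map stack into a 181-step sequence of 8 features for the LSTM — the
deliberate replacement of a large dense flatten, and the reason the model
fits a 2 MB flash.

## Size accounting: flash estimate vs. true parameters

Two counters coexist on purpose.

`flash_size_estimate()` reproduces the embedded deployment convention:
a conv layer counts `kernel_h · kernel_w · n_out · n_in` entries, the
reshape counts its output size, an LSTM counts flattened input length ×
hidden units, and a literal list of training variables (128, 20, 32) is
added; kilobytes assume 4 bytes per entry. For the default model this gives
30720 + 122880 + 1448 + 46336 + 180 = 201564 entries = 787.36 kb. The
convention ignores biases, LSTM gate quadrupling and the dense head — it is
a flash *budget*, reproduced exactly, not a parameter count.

`true_param_count()` does standard counting (conv `(kh·kw·n_in + 1)·n_out`,
dense `(in + 1)·out`, LSTM `4·((in + h + 1)·h)`) and must equal, entry for
entry, the number of weights the training engine materialises — asserted at
every model build. For the default model that is 159 512 parameters
(~623 KB at float32), comfortably inside the 2 MB flash constraint the
serialized-artifact test enforces.

Where the two conventions disagree, deployment decisions should use the
true count; the estimate exists because it is the convention the flash
budget was stated in.

## Training engine and its numerics

No deep-learning framework is available to R in this environment, so the
engine is part of the package: forward/backward passes for conv (as
time-shifted GEMMs where the kernel spans the full channel width, im2col
otherwise), LSTM (gates i, f, g, o; forget bias initialised to 1), dense
and activation layers in RcppArmadillo/R, verified against central finite
differences in the test suite. All randomness (Glorot initialisation,
shuffling, dropout) draws from R's RNG, so one seed fixes the entire run
bit-for-bit.

Optimization follows the deployment recipe: ADAM, initial learning rate
0.01 multiplied by 0.2 every 20 epochs, minibatches of 32 (128 conventional
for the pure CNN), up to 200 epochs, cross-entropy loss, early stopping
once training loss ≤ 0.01 *and* validation loss ≤ 0.1. Joint end-to-end
training is the default; a two-phase mode (SGDM warm-up, then ADAM) is
available for fidelity experiments. Validation runs once per epoch by
default, twice per epoch optionally.

Two numerical choices deserve a note, both made on small exploratory runs
and then fixed:

* **ADAM `eps = 1e-3`.** The second conv has fan-in 15 360, so its Glorot
  weights have scale ≈ 0.02 — the same magnitude as ADAM's per-coordinate
  step at lr = 0.01. With the textbook `eps = 1e-8` the optimizer shreds
  that layer within an epoch, the LSTM gates saturate, and training locks
  at the uniform-softmax fixed point. The larger `eps` keeps steps well
  below the learning rate wherever gradient magnitudes are small, which
  stabilises training at the configured rate without touching it.
* **Global gradient clipping (norm 1)**, the standard recurrent-net guard;
  on this problem it is rarely active but bounds worst-case steps.

The conv blocks include a leaky-ReLU activation. Without any conv
nonlinearity the two convolutions compose into one linear map feeding the
LSTM, and under the configured optimizer the model demonstrably stalls at
chance; a per-block activation is also simply how conv blocks are built in
this family of models.

## Splits and evaluation

**Intra-experiment**: each trial's raw signal is cut at the two-thirds
point *before* preprocessing — first two thirds to training, final third to
test — then each portion is conditioned independently and windowed.
Validation is the contiguous tail (10%) of the training portion's windows,
respecting temporal order; the fraction is a choice this package makes
(nothing prescribes one). **Inter-experiment**: one full protocol
repetition trains, another tests. A leakage guard asserts on every training
and evaluation run that no window (trial × start offset) appears in two
splits.

Evaluation produces the 16 × 16 confusion matrix (rows = truth), per-class
accuracies — a class absent from the test set reports `NA`, never 0 — and
overall accuracy = trace/total. The heat map display supports counts or
row-normalized percentages, since both conventions are common.
`compare_grid()` runs the feature × architecture cross product under a
fixed seed and reports accuracy alongside both size measures.

## The synthetic generator — what it does and does not show

`gesture_protocol()` emulates the acquisition sessions the pipeline
targets: 16 gestures × 6 channels at 2 kHz, 3 s holds with 1 s rests,
repeated 3 times (each repetition one "experiment"). Each gesture excites
each channel with a band-limited Gaussian carrier (bands spaced over the
physiological 20–450 Hz sEMG range) scaled by a per-gesture activation
weight and a 200 ms raised-cosine envelope, over a white noise floor
(relative amplitude 0.05). Gestures 7 and 8 share a carrier band and have
near-identical activation rows — a deliberately confusable pair standing in
for the index/middle-finger gestures that dominate real confusion matrices.
Channel RMS during a hold scales linearly with the activation weight, which
the tests verify to ±10%.

The generator produces stationary, additively mixed, noise-carrier signals.
Real sEMG is non-stationary within a contraction, exhibits electrode
crosstalk, fatigue drift, and inter-subject variability — none of which are
modelled. Passing the end-to-end test therefore demonstrates that the
pipeline is *correctly wired and trainable* under controlled conditions; it
says nothing quantitative about accuracy on human recordings.

Desk-scale problem sizes used by the tests: the default protocol yields
1440 windows (864/96/480 train/val/test) and the end-to-end check trains
the default model for at most 30 epochs under the standard early-stopping
rule. In practice dropout keeps the running training loss above the 0.01
target, so the run uses the full cap; validation loss settles around its
0.1 threshold from roughly epoch 8.

## Known limitations

* Offline only: zero-phase filtering and whole-segment normalization are
  incompatible with streaming inference.
* The engine is CPU-only and unoptimised beyond BLAS; it is a reference
  implementation, not a production trainer.
* The flash estimate reproduces an idiosyncratic convention; its totals are
  not trainable-parameter counts and should not be read as such.
* Scalar-feature tensors zero-pad 101 meaningful steps to 200, which wastes
  sequence capacity; this mirrors the fixed 200 × 6 × 1 input contract.
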