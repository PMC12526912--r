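---
title: "Methods: ECG conditioning, beat features and streaming classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG conditioning, beat features and streaming classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbeat)
```

This vignette explains the models and procedures implemented in `ecgbeat`,
the assumptions behind them, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about behaviour on real recordings.

## The problem

Beat-by-beat arrhythmia screening maps each QRS complex of a single-lead
ECG to one of the five AAMI classes (N, S, V, F, Q). Deployed against a
wearable stream, the classification must finish before the next beat
arrives; with normal inter-beat intervals of 0.6–1.0 s, 0.6 s is the
deadline `latency_report()` checks against. The pipeline has five stages —
conditioning, QRS detection, feature extraction, classification, streaming —
and every stage is exercised by tests on synthetic records with exact
ground truth.

## Synthetic ECG and what it does (not) emulate

`synth_record()` places beats at cumulative RR times drawn from a normal
distribution truncated at a 0.2 s physiological floor, assigns classes from
a configurable mix, and sums per-class templates built from Gaussian bumps
for the P wave, the Q/R/S deflections and the T wave. Class archetypes
follow clinical intuition: V beats are wide, tall, P-free and T-inverted;
S beats shorten their preceding RR interval to 60%; F beats sit midway
between N and V; Q beats are low-amplitude and featureless. Gaussian
broadband noise and a sub-0.5 Hz sinusoidal baseline are added on top, and
all three components are stored separately so denoising and baseline
removal can be scored against truth.

Defaults describe a realistic resting recording: mean RR 0.8 s, jitter
0.04 s, a class mix dominated by normal beats roughly in the proportions of
ambulatory arrhythmia data (89.4% N, 2.8% S, 7% V, 0.78% F, 0.02% Q), noise
at 2% of the R amplitude and 0.1 mV baseline wander at 0.3 Hz. The first
beat is placed at t = 1 s and a 0.5 s tail is kept beat-free so every beat
has a full morphology window.

What the generator does **not** emulate: inter-patient morphology
variability, electrode motion artefacts, rhythm context (bigeminy, runs),
class boundaries that overlap in feature space, and the severe class
imbalance interacting with hard examples. Tests passing on this data show
the *machinery* is correct (detection, indexing, retention, training,
streaming), not that real-data accuracies would be reproduced; full-scale
runs require the real database (see `load_ecg_dataset()`).

`synth_separable_features()` is a further simplification used only to
verify that the architectures can learn: each class is its z-scored
template plus isotropic noise at a level (sd 0.05) where a nearest-template
classifier is exact. The set is *separable by construction*; accuracy
reached on it measures optimisation health, not clinical difficulty.

## Conditioning chain

Order is fixed: resample → denoise → baseline removal → z-score.

* **Resampling** is band-limited (Fourier): the spectrum is truncated or
  zero-padded, splitting (upsampling) or folding (downsampling) the Nyquist
  bin so real signals stay real. Output length is `round(n·fs_out/fs_in)`.
* **Denoising** is VisuShrink: a 10-level db8 decomposition, noise scale
  `σ = median(|D1|)/0.6745` from the finest detail band only, universal
  threshold `σ√(2 ln N)`, soft thresholding of *all* detail bands, inverse
  transform. Estimating σ from D1 alone is the package's reading of the
  method; the alternative (per-level thresholds) is not implemented. For
  signals too short for 10 levels the depth is clamped with a warning, so
  short stream windows never fail.
* **Baseline removal** subtracts a trend built by a 71-sample median filter
  (despikes the QRS while following the isoelectric line) cascaded into a
  215-sample median filter (extracts the respiratory-scale drift). Edges
  use reflect padding, which avoids the amplitude bias of zero padding;
  trend estimates within about half a window of the record ends are
  accordingly less accurate, and tests score the interior.
* **Z-score** uses the population (1/n) standard deviation — the plain
  definitional form — and refuses constant signals.

### The wavelet transform

The DWT is implemented with zero extension: analysis is full convolution
with the decomposition filters followed by downsampling, so a level-1 band
of an n-sample signal holds `floor((n + f − 1)/2)` coefficients (98 for the
181-sample segments under db8). Two properties motivated this convention
over symmetric extension: energy is conserved *exactly* (the kept
coefficients are inner products with an orthonormal family covering the
zero-extended signal), and the adjoint — upsample, convolve with the
time-reversed filters, trim — is an *exact* inverse. The price is that
boundary detail coefficients of smooth signals are not zero (the padded
record has step edges); vanishing-moment behaviour holds for all interior
coefficients, and the tests assert exactly that.

## QRS detection and refinement

`pan_tompkins()` follows the classic stages: 5–15 Hz second-order
Butterworth band-pass, five-point derivative, squaring, 150 ms
moving-window integration, adaptive dual thresholds with exponential
signal/noise peak tracking, a 200 ms refractory period, and search-back at
half threshold when 1.66× the running RR average passes without a
detection. All filtering is **causal** — a deliberate choice so that
detections on a growing stream prefix reproduce full-record detections for
beats away from the stream head. Integrator peaks are mapped back to the
input grid by an argmax over the preceding 225 ms, and `correct_rpeaks()`
then refines every index to the local argmax in a ±20-sample window (ties
to the earliest sample; colliding corrections keep the earlier beat so RR
intervals stay positive).

## Feature extraction and retention

* **RR features** (9 per beat): the current, previous and next interval;
  each normalised by the mean of the 42 intervals strictly preceding the
  current one; previous/next normalised by the current; and
  `t_rr0 = (rr0 − avg)/sd` with the population sd of the same window.
  `t_rr0` is defined as 0 when the window sd is 0 — a perfectly regular
  rhythm is the reference state. A beat is retained when its previous and
  next beats exist and the full 42-interval history is available, so a
  record of B beats yields B − 44 rows; on long records retention lands
  near 89%, the familiar rolling-window cost.
* **Morphology segments**: 90 samples either side of the corrected peak at
  360 Hz (181 samples ≈ 500 ms); windows crossing a record boundary are
  dropped and counted. For network input the 181-sample segment is linearly
  resampled to the model's input length (default 100); both the raw and
  resampled forms are available. The 181-vs-100 bridge is a package
  decision: the printed network input is 100 wide while the stated window
  is 181 samples, and linear resampling preserves the beat shape at the
  cost of slight smoothing.
* **Wavelet features**: the deepest approximation band A_L of each segment
  (db8, level 1 by default → 98 coefficients), zero-padded to the fixed
  network width of 100. Level-1 db8 keeps the dominant beat morphology
  while halving dimensionality; deeper levels are configurable. Wavelet
  rows inherit the segment table's retention identically.

## Architectures, counting rules and training

Three architectures are built declaratively (`lstm_sequential_spec()`,
`bilstm_spec()`, `lstm_fcn_spec()`); `parameter_count()` evaluates
closed-form rules — LSTM `4(u(u+d)+u)`, bidirectional twice that, dense
`in·out+out`, Conv1D `in·k·f+f`, batch-norm `4·channels` including the two
running statistics — and the instantiated weight arrays are required (by
test) to match those totals exactly, including both 256- and 512-unit
variants. In the LSTM-FCN, the input is permuted so its timesteps become
channels of a length-1 sequence; a same-padded convolution on a length-1
sequence touches only the kernel tap aligned with the single valid
position, which the engine exploits while still counting the full kernel.

The training engine implements exact backpropagation (verified against
finite differences) with Adam (lr 0.001, ε = 1e−7), categorical
cross-entropy, Glorot-uniform kernels, per-gate orthogonal recurrent
matrices, forget bias 1, He-uniform convolution kernels, and batch-norm
with ε = 1e−3. Batch-norm running statistics use decay 0.9 so that
inference-time statistics adapt within a single short epoch; with slower
decays the statistics lag their initialisation over the few hundred
optimisation steps of a scaled-down run and inference quality collapses
while training accuracy is perfect.

Splits are stratified 70/30 at a fixed seed — stratification matters
because the Q class can be a handful of beats and an unstratified split can
lose it entirely; a class absent from the training split warns but stays in
the output space. Dropout 0.2 on the dense path of the sequential
architectures is available through `train_config()` and is off the
parameter tables (it has no weights); the LSTM-FCN carries its own 0.8-rate
dropout on the recurrent branch. Evaluation reports accuracy,
support-weighted precision/recall/F1 (macro averages alongside), and
per-class accuracy defined as per-class recall — the only per-class scalar
a single confusion matrix supports. Weighted averaging is used because
under heavy normal-class imbalance it is the convention whose summary
metrics track accuracy.

## Streaming

A `stream_session()` buffers incoming chunks and processes in rounds at
fixed stream times — every 2 s of buffered signal, the trailing 10 s window
is re-conditioned (z-score statistics are therefore window-local), QRS
complexes are detected, previously unseen peaks are registered (a new peak
must be more than 200 ms from every registered one), and every registered
beat old enough for its feature context is classified once, with batch
size 1 as the export contract requires. The maturity margin is 1.0 s for
segment-based features (right window plus T wave) and 1.6 s for RR features
(the next beat must exist), and RR features additionally wait for the
42-beat warm-up. Because rounds fire at fixed stream times, emitted beats
and labels are *exactly* invariant to the chunking of the input — the tests
assert identity across 0.5 s, 1 s and 5 s chunks. Agreement with the
offline pipeline is empirical rather than structural (window-local
normalisation and detector warm-up differ from the full-record run) and is
exact on clean synthetic records with a well-trained model.

`inference_s` records the per-beat share of feature extraction plus the
individual forward pass; `end_to_end_s` adds the per-beat share of window
conditioning. The 0.6 s compliance fraction reported by `latency_report()`
is measured on the machine running the session; desktop CPUs sit orders of
magnitude under the bound.

The HTTP layer (`ecg_service()`, `handle_request()`, `serve()`) keeps
sessions isolated by id and serialises predictions to JSON; `serve()` is a
deliberately small single-threaded development server, with the routing
logic fully testable in-process.

## Problem sizes used by the tests

The test-suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise every rule while staying desk-scale: records of
90–400 s, detector checks on ~120-beat records (three clean seeds plus a
noisy one at 5% of the R amplitude), 500-case property sweeps for the
wavelet and median-filter oracles, 100-record sweeps for the RR-feature
oracle, 5,000-beat training sets at 10 epochs for the learning checks, and
one 5-minute record streamed at three chunk sizes. Scaled-down training
accuracies on separable data (≥0.95 for LSTM-Sequential, ≥0.90 for all
three) verify the optimiser and architectures, not clinical performance.

## Known limitations

- The synthetic generator's class geometry is far cleaner than real
  inter-patient variation; real-data accuracy claims require the real
  database and full training.
- The zero-extension DWT trades clean boundary behaviour for exact energy
  conservation and exact inversion.
- Median-filter trend estimates degrade within half a window of record
  ends.
- `serve()` is single-threaded; concurrent clients are serialised, which
  bounds throughput but keeps sessions trivially isolated.
- Stream/batch label agreement is a property of model confidence; a model
  near chance can disagree across the two normalisation contexts even
  though both paths are individually deterministic.
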