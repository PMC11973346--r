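---
title: "Decoding multichannel neuromagnetic epochs with glcnet: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding multichannel neuromagnetic epochs with glcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements:
what is being modelled, which knobs matter, what the synthetic generator
does and does not emulate, and where the design was genuinely open and a
choice had to be made.

## The decoding problem

The input is an *epoch set*: `n` trials of a `C`-channel signal sampled at
`sfreq` for `T` samples, each trial labelled with one of `Nc` imagery
classes. The physiological signal of interest is event-related
(de)synchronization — a change of band-limited oscillatory power in a
task-specific frequency band over a task-specific subset of sensors. The
decoder therefore needs frequency resolution (which rhythm), spatial
resolution (which sensors, and how they co-fluctuate), and temporal
resolution (how power evolves within the trial).

## Architecture

`glcnet()` assembles three branches over a shared filter-bank front end.

**Filter bank.** Nine non-overlapping 4 Hz Chebyshev Type II band-passes
covering 4–40 Hz turn each epoch into a `(9, C, T)` tensor. Order and
attenuation are not dictated by the architecture itself; the defaults are
order 4, 30 dB stop-band attenuation, 2 Hz transition bands, applied
forward–backward so all band signals stay time-aligned (a causal
single-pass mode exists via `filter_bank(zero_phase = FALSE)`). These are
the conventional choices of filter-bank decoders (the FBCSP/FBCNet
lineage). Two numerical details matter on short epochs: filtering pads the
signal with an odd reflection whose length covers three time constants of
the filter's slowest pole, and the IIR state is initialized at the
steady-state response to the first sample, so a constant input produces
exactly its DC-gain response and no startup transient leaks into the
epoch. The designed magnitude responses can be audited on a grid with
`filterbank_response()`.

**Graph branch.** A temporal convolution (kernel `(1,10)`, 9 maps,
"same" padding, stride 1), batch-norm, `(1,10)` max-pool and dropout
produce per-channel feature vectors of length `T/10`. Two graph
convolutional layers (64 then 5 output features, ReLU) propagate them over
the sensor graph with the symmetric normalized operator
$\tilde D^{-1/2}(A+I)\tilde D^{-1/2}$, whose spectrum lies in $[-1, 1]$;
a channel-aggregating convolution (kernel `(C,1)`, 288 maps) then
collapses the channel dimension into feature map F1. The propagation rule
is sometimes printed elsewhere with $\tilde D^{+1/2}$ on the right; that
form is neither symmetric nor spectrally bounded, and this package
implements the standard symmetric normalization used throughout the GCN
literature.

**Sensor graph.** Two adjacencies are built in:

* `pli`: the phase lag index,
  $\mathrm{PLI}_{jk} = |\langle \operatorname{sign}\sin(\varphi_j -
  \varphi_k)\rangle|$, with phases from the analytic signal of each
  band-passed channel. PLI is insensitive to zero-lag coupling, hence
  robust to volume conduction/field spread. It is computed on the
  *training partition only* (no leakage into validation or test), with
  the first and last 5% of samples of each epoch discarded against edge
  effects, and averaged over the nine bands into one shared graph
  (per-band graphs would multiply parameters without a stated rationale).
* `distance`: $A_{jk} = 1 - d_{jk}$ with $d$ the min–max normalized
  pairwise sensor distance. Straight-line distance stands in for a scalp
  geodesic, which would need a head model the package does not assume; a
  precomputed geodesic matrix can be supplied via `custom_adjacency()`.
  When all pairwise distances are equal (two sensors), the normalized
  distance is defined as 0 and all off-diagonal affinities as 1.

Adjacencies are kept dense and unthresholded.

**Spatial branch.** A grouped spatial convolution (kernel `(C,1)`, 288
filters in 9 groups — 32 filters per band, so each filter sees exactly
one band) with ReLU and batch-norm, followed by non-overlapping averaging
over `avg_window` samples, yields F3 with `T/avg_window` time steps.
Because the averaging follows a rectifying nonlinearity, F3 encodes
band-specific spatially filtered signal *amplitude* over coarse time —
the ERD/ERS feature. The grouped layout is also what makes the layer's
parameter count (9·32·C + 288; 59,040 at C = 204) match the published
architecture table; an ungrouped convolution would not.

**LSTM branch.** F3, read as a sequence of `T/avg_window` vectors of
dimension 288, drives a single-layer LSTM (hidden size 32 by default)
with the standard gate recurrence, and a per-step linear readout maps the
hidden state back to 288 dimensions (F2). The published parameter count
for this layer (44,002) matches no standard gate parameterization — it is
not divisible by 4 — so the hidden size is exposed as a configuration
knob rather than pinned; likewise the first temporal convolution's
published count (8,109) is inconsistent with its stated kernel and map
numbers (which give 819) and is not asserted anywhere.

**Fusion and classifier.** F1 (shape `288 × 5`) is summed elementwise
with F2 and F3 (shape `288 × T/avg_window`). With the default
`avg_window = T/5` the shapes agree; otherwise F1 is linearly
interpolated along its second axis — the published description never
reconciles the two shapes, and interpolation is the least-surprising
resolution. The sum is flattened (1440 features by default) and mapped
linearly to `Nc` log-softmax outputs.

**Ablations.** `ablate(config, ...)` removes one branch's contribution
from the fusion: `module1_gcn` drops F1 together with the
temporal-convolution front end (nothing else consumes it);
`module2_spatialconv` drops F3 from the fusion but keeps the spatial
convolution alive because the LSTM input still needs it;
`module3_lstm` drops F2. The classifier width never changes.

## Loss and metrics

Both losses use natural logarithms and clip predicted probabilities at
$10^{-12}$. The enhanced cross-entropy
$H(p,q) = -\sum_x (1-q(x))^2\, p(x) \ln q(x)$ multiplies each term of the
cross-entropy by the squared complement of the predicted probability:
confident-correct trials contribute almost nothing, hard trials dominate.
For one-hot targets it reduces to a focal-style term on the true class
and is never larger than the plain cross-entropy — a property the test
suite checks over random cases, along with the closed-form spot values.
(Some descriptions of this loss speak of a "square root"; the formula is
a square, and the square is what is implemented.) Multi-class F1 is
macro-averaged — the unweighted mean of per-class one-vs-rest F1 — since
the binary formula does not say how to pool classes and the class design
here is balanced. Cohen's kappa uses
$p_e = \sum_k \text{row}_k\,\text{col}_k / n^2$, with $\kappa \equiv 0$
when $p_e = 1$.

## Two-stage training

Stage 1 optimizes the chosen loss on the training partition (Adam,
batch 32, learning rate $10^{-3}$, default moment coefficients, no weight
decay; batches reshuffled each epoch, last short batch kept). After every
epoch the validation accuracy is computed; *improvement* means strictly
greater than the best so far, ties do not reset the patience counter.
When `patience` epochs pass without improvement (or the epoch cap is
reached), the weights — including batch-norm running statistics — of the
best epoch are restored. Stage 2 merges the validation trials into the
training set, remembers which trials they were, and keeps optimizing
while monitoring the loss on exactly those trials; it stops as soon as
that loss falls below the *minimum* stage-1 validation loss. Because that
criterion may never fire, a safety cap (`max_epochs_stage2`) guarantees
termination and the history records whether the criterion was met.
Everything stochastic — initialization (uniform fan-in scaling), dropout
masks, shuffling, splitting, generation — draws from the session RNG, so
one seed reproduces a run bit-for-bit.

## The synthetic generator

`generate_epochs()` emulates the features of imagery data the decoder
relies on: each trial is unit-RMS $1/f$ background on every channel plus
white sensor noise, and trials of class $k$ additionally carry a
narrow-band oscillation (band-passed white noise, not a pure tone, so
trials vary realistically) on that class's channel subset, scaled so its
RMS is `modulation_depth` times the background's in-band RMS there.
Channels within a class share the waveform with a constant
`coupling_lag_deg` phase lag, giving PLI estimation a known ground truth.
Labels are exactly balanced.

Default study conditions (the desk-scale benchmark): 32 channels at
250 Hz, 2 s epochs (T = 500), 4 classes × 100 trials, class bands
(8–12), (12–16), (20–24), (28–32) Hz on disjoint 8-channel blocks,
modulation depth 3, noise σ = 0.5, 90° coupling lag, background exponent
1. The architecture scales with the data while preserving every shape
relation of the full-size model (pool 10, five fused time steps, 288
spatial filters in 9 groups), so the desk model is the same topology at
C = 32 instead of 204. What the generator does *not* emulate: realistic
sensor geometry or head-model field spread, non-stationary artifacts,
inter-subject variability, class overlap on shared channels. Passing the
end-to-end test therefore shows the pipeline recovers planted structure
of the kind the model assumes — not that it attains any particular
accuracy on real recordings.

Desk-scale training protocol: the full-size defaults (patience 50 within
100 stage-1 epochs) are sized for thousands of real trials; the benchmark
runs converge within a handful of epochs, so the end-to-end experiments
use stage-1 cap 8 with patience 5 and a stage-2 cap of 3 (the null
control, which cannot converge, uses caps 3/1). Problem sizes in the test
suite follow the same logic: oracle comparisons run on 2–8-channel
instances where brute force is exact and instant.

## Numerical choices

* Batch-norm uses biased batch variance, $\varepsilon = 10^{-5}$, and
  running statistics with momentum 0.1 (training mode normalizes by batch
  statistics; evaluation uses the running ones, making eval-mode forward
  a pure function of weights and input).
* Argmax ties in prediction break toward the lower class index.
* The forward/backward engine is hand-derived, vectorized over BLAS with
  a few C++ kernels for the convolution and normalization hot paths, and
  is verified against finite-difference gradients and scalar-loop oracles
  in the test suite. Gradient checks avoid parameters sitting exactly on
  a ReLU kink (zero-initialized biases with rectified-dead inputs), where
  the loss is genuinely non-differentiable and any subgradient is valid.
* Checkpoints (`save_glcnet()`) use R's native serialization and carry
  weights, configuration (including the adjacency), batch-norm state and
  seed.

## Known limitations

* No FIF reader: epochs are interchanged as HDF5; converting from raw MEG
  formats (and all raw-data preprocessing — Maxwell filtering, ICA, head
  movement compensation) is upstream of this package.
* Single-layer unidirectional LSTM only; no attention, no augmentation.
* The graph is static per fit; dynamic or learned connectivity is out of
  scope.
* Training is single-threaded and in-memory; the intended regime is
  hundreds-to-thousands of trials, not continuous recordings.
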