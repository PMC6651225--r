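---
title: "Decoding motor imagery EEG with capsule networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery EEG with capsule networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imagining a left- or right-hand movement attenuates the mu (8–12 Hz) and
beta (16–31 Hz) rhythms recorded over the sensorimotor cortex — the
event-related desynchronization (ERD) — most strongly over the hemisphere
*contralateral* to the imagined hand. A brain–computer interface can
decode the imagined side from three electrodes (C3, Cz, C4) by detecting
which hemisphere desynchronized. `micaps` implements a complete decoding
pipeline around a capsule network classifier:

1. band-pass filter the raw trial to 4–38 Hz and cut the 0.5–2.5 s
   post-cue epoch (500 samples at 250 Hz);
2. convert each 3 × 500 epoch to a 3-channel 14 × 14 time–frequency image
   by short-time Fourier transform (STFT) and mu+beta band cropping;
3. classify the image with a capsule network trained by dynamic routing,
   a margin loss on capsule norms, and a reconstruction regularizer.

A synthetic ERD trial generator stands in for real recordings so that the
entire pipeline — including training — is testable on a desktop in
minutes.

## The synthetic generator

`synthesize_trial()` draws white Gaussian noise per channel and adds mu
(10 Hz) and beta (22 Hz) sinusoids with per-trial random phases to all
three channels:

$$x_c(t) = \varepsilon_c(t) + A_\mu\, g_c(t) \sin(2\pi f_\mu t + \varphi)
         + A_\beta\, g_c(t) \sin(2\pi f_\beta t + \psi),$$

where the gain $g_c(t)$ equals $1 - d$ on the channel contralateral to
the labeled hand (left hand → C4, right hand → C3) inside the ERD window
and 1 elsewhere. Cz is never attenuated, so it carries no class
information. Defaults: 8 s trials, cue at 3 s, ERD window 0.3–2.8 s
post-cue (chosen to fully cover the 0.5–2.5 s analysis epoch),
$A_\mu = A_\beta = 1$, noise SD 0.5, depth $d = 0.8$.

Deliberate simplifications: the noise is white rather than 1/f, there is
no post-imagery ERS rebound (the analysis window ends before rebound
would matter), no volume conduction, eye/muscle artifacts, or
inter-trial amplitude variability. Passing tests on this fixture
therefore demonstrate that the implementation learns the contralateral
power asymmetry it was given — not that the architecture reaches any
particular accuracy on real recordings, whose SNR the generator does not
attempt to calibrate.

The `band_power()` helper integrates one-sided periodogram ordinates over
a frequency band, so a unit in-band sinusoid yields ≈ 0.5 (its mean
square). It is the spectral oracle used by the package's own simulation
checks: e.g. the contralateral/ipsilateral mu power ratio in a noise-free
trial equals $(1-d)^2$ exactly.

## Preprocessing choices

The band-pass filter is a 4th-order Butterworth applied
forward–backward (`signal::filtfilt`), i.e. zero phase, so ERD latencies
are not displaced; this is standard EEG practice. Filtering is applied to
the *full* trial before epoching, keeping filter edge transients outside
the 2 s analysis window (the tests demonstrate that the opposite order
differs near the epoch edge). A zero-phase cascade of two 4th-order
passes has a finite transition band: for white-noise input a few percent
of power survives just beyond 4–38 Hz, falling below 1% beyond a ~2 Hz /
~12 Hz margin.

Indexing is 0-based and half-open: the epoch is samples
$[\,\mathrm{cue} + \lfloor 0.5 f_s \rceil,\ \mathrm{cue} + \lfloor 2.5
f_s \rceil\,)$, exactly 500 samples at 250 Hz. Channel order (C3, Cz,
C4) is fixed end-to-end; archives with a different order are rejected
rather than silently reordered.

## STFT imaging

Frames of 128 samples with 100 samples of overlap (hop 28) are tapered
with a periodic Hann window and transformed with a one-sided DFT; no
boundary padding is used and a trailing partial frame is dropped, so a
500-sample epoch yields exactly $\lfloor(500-128)/28\rfloor + 1 = 14$
frames and $128/2+1 = 65$ frequency bins of spacing
$250/128 = 1.953$ Hz. Cropping rows 5–18 (1-based; ≈ 7.81–33.20 Hz)
keeps the 14 contiguous bins covering mu and beta, producing a square
3 × 14 × 14 magnitude image.

Two open conventions were settled as follows. The window length is 128
samples: 65 one-sided bins require a 128-point DFT and 14 frames from
500 samples require hop 28 = 128 − 100; a 140-sample window is
incompatible with both printed shapes, though `stft_config()` accepts any
window length. Magnitudes are linear (not log-scaled, not power) and each
image is min–max normalized to [0, 1] *jointly* over its three channels;
the [0, 1] range matches the logistic output of the reconstruction
decoder. A constant image maps to all zeros.

## The capsule network

For a 3 × 14 × 14 image the default architecture is:

* 3 × 3 convolution, stride 1, 4 channels, SELU activation
  ($\lambda = 1.0507$, $\alpha = 1.6733$, the standard self-normalizing
  constants) → 4 × 12 × 12;
* primary capsules: a 3 × 3 / stride 2 convolution with
  $128 \times 4 = 512$ maps → 5 × 5 grid, reshaped to
  $128 \cdot 25 = 3200$ capsules of dimension 4, each passed through the
  squash non-linearity $v = \frac{\|s\|^2}{1+\|s\|^2}\frac{s}{\|s\|}$;
* one 8-dimensional class capsule per class (left / right), coupled by
  dynamic routing by agreement: starting from zero logits, repeat $r$
  times (default 1) — couplings $c_{ij} = \mathrm{softmax}_j(b_{ij})$,
  weighted sums $s_j = \sum_i c_{ij}\hat u_{j|i}$ with prediction
  vectors $\hat u_{j|i} = W_{ij} u_i$, outputs $v_j = \mathrm{squash}(s_j)$,
  updates $b_{ij} \mathrel{+}= \hat u_{j|i}\cdot v_j$;
* margin loss
  $L_k = T_k \max(0, m^+ - \|v_k\|)^2 + \lambda (1-T_k)\max(0, \|v_k\| -
  m^-)^2$ with $m^+ = 0.9$, $m^- = 0.1$, $\lambda = 0.5$;
* a reconstruction decoder (512 → 1024 → 588 units) fed the class
  capsules with all non-selected capsules zeroed; its summed squared
  pixel error is added to the loss with weight 0.0005.

Design points that were genuinely open and how they were fixed:

* **Primary capsule grouping.** The 512 primary maps are grouped as 128
  channels × 4 dimensions (dimensions contiguous within a channel), and
  squash is applied per capsule. This is the reading that reproduces
  "128 channels of four-dimensional capsules" from a convolutional
  layer.
* **Routing weights** $W_{ij}$ are distinct per (input capsule, class)
  pair — no weight sharing — following the original capsule formulation.
  Logits $b$ reset to zero on every forward pass.
* **Backpropagation through routing** is exact: the routing loop is
  unrolled and differentiated, including the agreement updates (for
  $r = 1$ the couplings are constants and the loop degenerates to a
  uniform average). Finite-difference tests pin every gradient path to a
  relative error below $10^{-4}$.
* **Decoder activations**: rectifiers on the hidden layers and a
  logistic output so reconstructed pixels lie in (0, 1), matching the
  normalized images; reconstruction error is the summed squared
  difference. During training the decoder is masked by the true label;
  at evaluation by the predicted label.
* **Initialization**: routing weights $\mathcal N(0, 0.1^2)$;
  convolution and dense weights fan-in-scaled Gaussians. Fully seeded.
* **Ties** in the class-norm argmax break toward the lower index; with
  balanced evaluation sets this cannot bias accuracy.
* **Precision**: all arithmetic is 64-bit double (R's native numeric);
  single-threaded runs are bit-reproducible for a fixed seed.

## Training protocol

`train_model()` implements classical (heavy-ball) momentum SGD on the
mean per-sample total loss: batch size 50, learning rate 0.01, momentum
0.7, 500 epochs by default, per-epoch reshuffling driven by the seed, and
the final short batch is used rather than dropped. Accuracy is
$1 - $ misclassification rate. With early stopping enabled, the last 20%
of trials per class are held out, training stops when validation loss
has not strictly improved for `patience` consecutive epochs, and the
best-validation parameters are returned; without it, the final-epoch
parameters are returned. `grid_search()` sweeps routing iterations
(1–3), reconstruction on/off, and the layer-size grid with a shared
seed, returning a table sorted by test accuracy; because reconstruction
is a grid axis, matched rows give the signed accuracy effect of the
regularizer.

The ShallowNet baseline consumes raw 3 × 500 epochs: temporal
convolution (40 kernels, 1 × 25) → spatial convolution over all
electrodes (40 kernels, 3 × 1) → batch normalization → squaring →
average pooling (1 × 75) → log → dropout → dense softmax. The pooling
stride is not derivable from the layer table alone; stride 100 is the
unique choice under which the pooled output has 5 frames and the
flattened size is 200, and is used here. Dropout defaults to 0.5 and the
log is clamped at $10^{-6}$ so an all-zero epoch stays finite. Its
gradients (including batch normalization) are likewise hand-derived and
finite-difference tested; note the convolution biases ahead of batch
normalization receive provably zero gradient.

## Problem sizes used by the tests and the acceptance script

The discriminability study trains the default capsule network for 100
epochs on 100 + 100 strong-effect trials (depth 0.8, noise SD 0.3) and
evaluates on an independent 200-trial set, where it should exceed 90%
accuracy; an identically sized null study (depth 0) must stay inside the
central 99% binomial band around chance at $n = 200$. Convergence shape
is checked on the same fixture: training loss at every epoch ≥ 20 below
the epoch-1 loss, with and without reconstruction (25 epochs suffice for
the latter). Oracle equivalence uses 10 random routing instances with at
most 10 input capsules and 3 iterations against an independent
straight-loop implementation at $10^{-10}$; gradient checks sample ~24
parameters of a compact configuration with 2 routing iterations. These
sizes keep a full run in minutes on one CPU while leaving every model
component active.

## Known limitations

* The generator's idealized ERD makes the classification task easier
  than real EEG; accuracies on this fixture say nothing quantitative
  about benchmark recordings.
* Only two classes and three channels are supported; EM routing, matrix
  capsules, stacked capsule layers and wavelet imaging are out of scope.
* Archives use R native serialization (a documented single-file layout);
  recordings in other formats enter through the pluggable reader hook of
  `ingest_recording()`.
* Training is CPU-bound vectorized R; it is sized for hundreds of
  trials, not the thousands of a multi-session BCI study.
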