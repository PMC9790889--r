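---
title: "Methods: filter-bank CSP, Hilbert envelopes and the fuzzy convolutional recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filter-bank CSP, Hilbert envelopes and the fuzzy convolutional recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegclfcnet)
```

## The problem

Cued motor imagery (imagined left-hand, right-hand, foot or tongue
movement) modulates band-limited sensorimotor EEG rhythms: the mu band
(8–12 Hz) and the beta band (around 20–24 Hz) show event-related
(de)synchronization with class-specific spatial topographies. A
motor-imagery brain–computer interface must turn a short multi-channel
epoch into one of K class labels. This package implements a complete
pipeline for that task:

1. **Filter bank**: nine 4-Hz-wide band-pass filters spanning 4–40 Hz.
2. **Multi-scale time steps**: optional sub-windows of each trial
   (seven intervals between 2.5 and 6 s of the trial timeline) so that
   subject-specific response latencies are captured.
3. **Common spatial patterns (CSP)** per (band, window, class contrast):
   spatial filters maximizing the variance ratio between one class and
   the rest, from a generalized eigendecomposition of trace-normalized
   class covariances.
4. **Hilbert envelopes** of the spatially filtered signals, low-pass
   filtered at 4 Hz and resampled so every window contributes the same
   number of time points (40 by default).
5. **EEG-CLFCNet**: a compact depthwise/separable CNN feature extractor,
   an LSTM over the pooled feature sequence, and two parallel heads — a
   fully connected branch and a fuzzy neural block (FNB) — merged into a
   softmax classifier.
6. **Hyperparameter tuning** of the three convolutional size parameters
   by coordinate descent or Gaussian-process Bayesian optimization, both
   scored by stratified cross-validation.

## The model components and their assumptions

### CSP and its numerical policy

For classes $i, j$ with averaged trace-normalized covariances $R_i, R_j$,
CSP solves $R_i W = (R_i + R_j) W D$; filters at the two eigenvalue
extremes maximize/minimize the variance ratio. Each trial covariance is
normalized by its trace, so the estimate is invariant to per-trial
amplitude.

Narrowband covariances of short epochs are nearly rank-deficient: within
a 4-Hz band, a handful of oscillatory sources carry almost all the power,
and the composite $R_i + R_j$ has a cluster of near-zero eigenvalues.
Whitening by the composite then amplifies estimation noise in those empty
directions by orders of magnitude, and the extreme filters fill up with
spurious components. The solver therefore caps the whitening condition:
composite eigenvalues below `cond_tol = 0.05` of the largest are floored
before inversion (a 20:1 condition cap). Empirically the composite
spectrum of band-passed epochs shows a gap of two orders of magnitude
between signal and background directions, so any cap between roughly
0.005 and 0.3 behaves identically; 0.05 sits in the middle of that
plateau. For well-conditioned covariances the floor is inactive and the
solution is the exact generalized eigendecomposition — the unit tests
verify 1e-8 agreement with a brute-force solver on such inputs. A small
shrinkage toward the scaled identity (`1e-6`) guards against exactly
singular inputs; ties in eigenvalues are broken by solver order, and each
filter's largest coefficient is made positive so results are
reproducible.

The multi-class extension uses one-vs-rest contrasts (the filter-bank CSP
convention); pairwise contrasts are available. `m` filters are taken from
each spectral end (default 2; the full-pipeline helpers default to 1 to
keep desk-scale runs compact).

### Envelope features

The analytic signal is computed by the frequency-domain method (zeroing
negative frequencies); its modulus is the instantaneous amplitude.
Because envelope content is slow, it is low-pass filtered at 4 Hz
(zero-phase Butterworth) and resampled to exactly `n_points = 40` values
per window regardless of window duration, at window-centered time points.
The implied output rate must stay at or above the 8 Hz Nyquist rate of a
4-Hz envelope; violations raise an error rather than aliasing silently.
Envelopes are computed with 10% odd-symmetric reflective padding because
the discrete Hilbert transform is unreliable at the window edges.

Zero-phase filtering is implemented in the frequency domain: the spectrum
is multiplied by $|H(\omega)|^2$, the response that forward–backward
application of the designed Butterworth filter realizes, on a padded FFT
whose length is chosen 2-3-5-smooth. This gives identically zero phase,
lets one padded transform be shared by all nine bands of the filter bank,
and is verified in the tests against tone retention/rejection and a
transfer-function oracle.

### The network

The compact CNN follows the depthwise/separable design for EEG: a
temporal convolution (`F1` kernels of length 64, same padding, no bias)
acting as a learned filter bank; batch-norm; a depthwise spatial
convolution (one `C x 1` kernel per temporal filter, depth `D`) acting as
learned spatial filters; batch-norm, ELU, average-pool 4, dropout 0.5; a
separable convolution (`F2` pointwise outputs after a length-16 depthwise
kernel); batch-norm, ELU, average-pool 8, dropout. All convolutions are
bias-free and batch-norm carries two trainable parameters per map — the
only reading consistent with the reference parameter counts (512, 16,
352, 32, 384, 16 with flatten width 72 for a 22 x 288 input), which the
acceptance tests pin down cell by cell.

The pre-flatten feature map (`F2` maps over the pooled time axis) is
treated as a feature sequence and fed to an LSTM. The classical gate
equations apply; two candidate modes are provided. The default
`tanh_standard` mode uses its own candidate weights with tanh and
`h = o * tanh(c)`; `linear` mode retains the literal linear
candidate and `h = o * c` for comparison experiments. The hand-computed
zero-parameter case (all gates at 0.5, `c_t = 0.5 c_{t-1}`,
`h_t = 0.25` for unit cell state) is a frozen test.

The fuzzy neural block computes, for each of `K` rules, the Gaussian
membership of the last LSTM state $v$ to a centroid $c^k$:
$\mu_j^k = \exp(-(v_j - c_j^k)^2 / (4\alpha_j^2))$, combines memberships
across dimensions with a product t-norm, and normalizes across rules.
Products are computed in the log domain with a log-sum-exp
normalization, so high-dimensional inputs cannot underflow into a 0/0.
The scaling vector $\alpha$ is trained by backpropagation (kept positive
by clipping at 1e-3); the centroids are *not* gradient-trained: they
start at zero for the first epoch and are refreshed between epochs by
fuzzy c-means (fuzzifier 2, via `e1071::cmeans`) on the buffered LSTM
states of the preceding epoch. Both heads (an ELU fully connected branch
and the FNB) feed a merged dense softmax layer; concatenation is the
default merge, with an elementwise sum available when the branch widths
agree. Disabling the FNB reproduces the ablation variant and changes
only the head's parameter count.

All forward/backward passes are hand-derived and verified by central
finite differences at 1e-4 relative tolerance (in practice they agree to
about 1e-8), including the gradients with respect to $\alpha$ and the
centroids. Training is minibatch Adam (default rate 3e-3) on
cross-entropy; a fixed seed makes runs bit-reproducible, including
dropout masks, shuffling, and the c-means refresh.

### Network input modes

The reference architecture consumes raw `channels x samples` epochs,
while the pipeline described above produces CSP-envelope features; both
input modes are therefore first-class here. `raw` mode reproduces the
reference table exactly (used for architecture checks and per-electrode
evaluation, where CSP is impossible on a single channel). `envelope`
mode — the default of the end-to-end helpers — reshapes the envelope
tensor to components x time; its defaults shorten the temporal kernel to
9 taps (0.9 s of 10-Hz envelope context) and use pool widths of 2,
because 40-point envelope windows leave no room for the raw-mode
64-tap/4 x 8-pool geometry.

## The synthetic-data generator

The generator emulates one session of a four-class cued motor-imagery
recording: 4 classes x 72 trials, 22 channels at 250 Hz, 4 s of imagery
per epoch (optionally preceded by 2 s fixation and a 1.25 s cue so the
2.5–6 s analysis windows can be indexed). Each class owns one latent
filtered-noise oscillator band-passed to its class band — 8–12 Hz for
classes 0/1, 20–24 Hz for classes 2/3 — whose standard deviation is
scaled by `class_gain = 2` on that class's trials during the imagery
window. Sources are mixed into channels through a seeded random
orthonormal matrix (one distinct spatial pattern per class; an explicitly
scalp-lateralized layout would add realism but nothing CSP-relevant at
this scale), plus white or 1/f ("pink", the standard EEG background
model) channel noise scaled to the configured broadband SNR. The same
seed yields a bit-identical session, and the mixing matrix travels with
the recording so parameter-recovery tests can compare CSP filters to the
true unmixing directions.

What the generator does **not** emulate: volume-conducted correlated
background, ocular/muscular artifacts, non-stationary drift across a
session, or inter-subject variability. Passing tests on this data shows
that the pipeline recovers planted spatio-spectral structure at realistic
SNR; it does not certify benchmark accuracy on real recordings, which
requires the external competition dataset.

One consequence of the clean generator deserves emphasis: classification
on default-size sessions saturates near 100% for broadband SNRs from 0 to
12 dB, because in-band the planted sources always dominate. The SNR
monotonicity study therefore uses deliberately harder conditions (24
trials per class, 3 folds, a brief 5-epoch schedule) chosen so accuracy
sits well off ceiling and the SNR effect is measurable; with three seeded
repetitions the mean accuracy rises cleanly with SNR.

## Desk-scale study sizes

The checks that train networks choose sizes that keep the full test suite
and the acceptance script comfortably inside a single-CPU run:

- architecture/kappa/solver/envelope checks: closed-form, sub-second;
- CSP recovery: five full-size sessions, one band;
- end-to-end: one default session (288 x 22 x 1000, 10 dB), 10-fold CV,
  15 training epochs — mean accuracy around 0.99;
- chance control: the same session with permuted labels, 3 folds;
- SNR sweep: as described above;
- tuners: analytic objectives with exhaustive or dense-grid oracles, plus
  a small cross-validated objective with fold seeds fixed inside the
  objective so re-evaluation of the returned configuration is exact.

## Design choices where the design was genuinely open

- **Averaged covariance**: the mean of per-trial trace-normalized outer
  products, the only reading that yields a covariance.
- **Filter family**: 4th-order Butterworth, zero-phase — the filter-bank
  CSP convention.
- **Interval reference**: analysis windows are interpreted relative to
  trial start (so 2.5 s is 0.5 s after the cue given 2 s fixation);
  the reference frame is configurable.
- **Sample rounding**: window start index is `round(start * fs)`, length
  `round(duration * fs)`, half-open — lengths, not endpoints, drive
  downstream shapes.
- **2M filters per block**: every (band, window, contrast) keeps the `m`
  filters from each eigenvalue end, so features count contrasts x 2m
  components.
- **Head sizes**: LSTM units (16), fuzzy rules (8) and the fully
  connected branch width (16) are exposed as configuration/tuning
  parameters.
- **Tuner internals**: expected improvement (xi = 0.01) over a Matern-5/2
  Gaussian process on unit-normalized coordinates, length-scale chosen by
  marginal likelihood on a small grid, integer parameters relaxed and
  rounded at evaluation.
- **Container and I/O**: sessions are stored in a single-file,
  schema-versioned container on R's native serialization, with
  invariants re-validated on load. EDF/EDF+ recordings can be imported
  (events from the annotations channel; the sampling rate is read from
  the file and never silently resampled); GDF is rejected with a clear
  error since no parser is bundled.

## Known limitations

- Training is single-threaded CPU R; minutes per cross-validated session
  rather than seconds. The layer stack is batched matrix algebra, not a
  general autodiff framework.
- The per-electrode evaluation protocol rebuilds the raw-mode network
  with one input channel; region-level numbers are therefore comparable
  only within this package's protocol.
- The c-means centroid refresh is a heuristic; with very small training
  sets the rule activations can be near-uniform and the fuzzy head then
  contributes little beyond the fully connected branch.
- Frequency-domain zero-phase filtering matches forward–backward IIR
  filtering up to edge treatment; both are approximations near window
  boundaries, which is why envelopes are computed on padded windows.
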