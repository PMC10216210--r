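---
title: "Filter-bank complex-spectrum SSVEP decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-bank complex-spectrum SSVEP decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the signal model, the decoder, the hyperparameter search, the choices made
where the design was genuinely open, and what the synthetic benchmark does
and does not show about real EEG.

## The decoding problem

A steady-state visual evoked potential (SSVEP) is the oscillatory response
of visual cortex to a flickering stimulus: the EEG over occipital
electrodes carries power at the flicker frequency and its harmonics, with
a phase tied to the stimulus phase. An SSVEP brain–computer interface
presents $N$ targets flickering at distinct frequencies $f_k = f_0 +
(k-1)\Delta f$ (often with phases $\phi_k = \phi_0 + (k-1)\Delta\phi$) and
must decide, from a short multi-channel EEG window, which target the
subject is fixating. Two stimulus grids are built in as presets: a
12-target grid (9.25–14.75 Hz in 0.5 Hz steps, phases stepping by
$0.5\pi$) and a 40-target grid (8–15.8 Hz in 0.2 Hz steps).

## Pipeline and its parameters

### Filter bank

Each trial is decomposed into $N_{fb}$ sub-bands by band-pass filters with
passbands $[n \times 8, 88]$ Hz, $n = 1 \dots N_{fb}$ — the band plan
standard in filter-bank SSVEP analysis, which lets the fundamental and
successive harmonic bands be weighted separately by the classifier.
Publications in this lineage rarely state the filter realization, so the
package fixes one and documents it:

* Chebyshev Type I IIR, order selected per band from a passband ripple of
  3 dB, stopband attenuation of 40 dB, lower stopband edge
  `max(low − 4, 2)` Hz and upper stopband edge 94 Hz (all configurable).
* Zero-phase application: forward–backward filtering with odd-symmetric
  edge padding of length 3 × (filter order) and steady-state (DC-matched)
  initial conditions. The padding plus matched initial conditions keep the
  near-unit-circle poles of the sharp band edges from ringing into the
  epoch; the realized response is the squared magnitude with zero phase,
  which the tests verify by a zero-lag cross-correlation peak.
* A sampling rate at or below 2 × 88 Hz is an error, not a silent clip:
  a band plan that cannot be realized should fail loudly.

The filter bank runs on the full trial *before* windowing, so 1 s windows
carry no per-window filter transients.

### Complex-spectrum features

Each 1 s window is zero-padded (rectangular window, no taper — this keeps
the discrete Fourier transform exactly equal to its defining sum, which
the tests exploit) to the smallest length reaching the requested
frequency resolution: `fft_length = ceiling(fs / 0.293)`, i.e. 874
samples at 256 Hz for a realized resolution of 0.2929 Hz. The retained
band is 3–35 Hz; bins are selected by nearest bin index,
`round(f_lo/df) .. round(f_hi/df)`, which yields `NFFT = 110` components
per channel per band at the defaults — the value consistent with the
feature-width arithmetic of the complex-spectrum CNN lineage
(`8 × 660` for 8 channels, 3 bands). A strict "bin centre inside
[3, 35]" rule would give 109 bins and break that arithmetic, which is why
the nearest-bin convention was chosen. Real parts of all retained bins
come first, then imaginary parts, bands concatenated in ascending order;
a column descriptor records (band, part, frequency) for every column.

No feature normalization is applied before the network: normalization is
the network's own batch-norm layers' job.

### The network

Input is the $N_{ch} \times (2 \cdot \mathrm{NFFT} \cdot N_{fb})$ feature
matrix. Layer 1 applies $N_{k1}$ kernels of shape $N_{ch} \times 1$ at
stride 1 — a learned spatial filter per output map, mixing all channels at
each frequency column. Layer 2 applies $N_{k2}$ kernels of shape $1
\times K_2$ at stride $S_2$ across the width, producing
$\lfloor (2 \cdot \mathrm{NFFT} \cdot N_{fb} - K_2)/S_2 \rfloor + 1$
positions per map, so the dense output layer sees

$$N_f = \left(\left\lfloor \frac{2\,\mathrm{NFFT}\,N_{fb} - K_2}{S_2}
\right\rfloor + 1\right) \times N_{k2}$$

values — a closed form the tests check against the realized forward pass
for randomized hyperparameter sets. Structural constraints: $K_2$ may not
exceed the feature width and $S_2$ may not exceed $K_2$ (a stride beyond
the kernel would skip inputs entirely).

Choices the architecture definition leaves open, fixed here as the conventional
ones: per-layer operation order conv → batch-norm → PReLU → dropout;
softmax cross-entropy loss; one learnable PReLU slope per layer
initialized at 0.25; seeded He-uniform weight initialization; Adam at
learning rate 0.001; dropout rate 0.5; batch-norm $\epsilon = 10^{-5}$
with running statistics (momentum 0.1) used at inference. Training runs
50 epochs at batch size 32; the report carries the final epoch's training
accuracy and loss and the window-level test accuracy.

The forward/backward pass is compiled (RcppArmadillo) with an internal
xorshift128+ RNG for dropout masks and shuffling, seeded from R's RNG
stream, so a single `set.seed()` makes training bit-reproducible; the
compiled path is cross-checked in the tests against a pure-R reference
implementation and against finite-difference gradients.

### Protocol

Trials are split at the *trial* level before any windowing (12 train /
3 test per class in the standard 15-block design), stratified per class
and seeded; no 1 s window of one trial can land on both sides, which the
tests verify by source-trial bookkeeping. Windows are 1 s with a 0.1 s
stride. At 256 Hz the stride is 25.6 samples; window $k$ starts at sample
$\mathrm{round}(k \times 25.6)$, accumulating the fractional stride
rather than rounding the stride itself, which yields the full
$\lfloor (L - W)/(0.1 f_s) \rfloor + 1 = 31$ windows per 4 s trial that
explicit enumeration gives (a constant 26-sample stride would lose one).
Accuracy is counted per window — each 1 s window is one classification.
For real recordings, the stimulus-onset lead-in is dropped before
decoding: 0.135 s for the 12-target recordings, 0.5 s cue + 0.14 s
latency for the 40-target benchmark (the latter following that dataset's
own documentation).

### The hyperparameter search

The search ("artificial gradient descent") assigns each searched
hyperparameter a three-candidate triple $(k, 2k, 8k)$ — base $k =
N_{ch}$ for $N_{k1}, N_{k2}, K_2$ — and evaluates the full Cartesian
product each round (3⁵ = 243 models in round 0). Two representation
decisions matter:

* **The stride is searched as a ratio of $K_2$** with candidates
  $(1/8, 1/4, 1)$. Realizing $S_2 = \mathrm{round}(\rho \cdot K_2)$ per
  combination keeps every one of the 243 products valid ($S_2 \le K_2$ by
  construction); an absolute stride grid would invalidate a third of the
  product. Hand-built absolute grids remain supported, with violating
  combinations dropped and counted.
* **$N_{fb}$ is searched over the explicit list $\{1, 3, 7\}$** — the
  values this field actually uses — and is frozen at a seed set's value
  between rounds rather than ratio-updated.

After a round, the marginal trend of each hyperparameter at each selected
seed set (the three combinations differing only in that coordinate) picks
the update rule: strictly rising → shift up $(a_2, 2a_2, 8a_2)$; strictly
falling → shrink $(a_0/8, a_0/2, a_0)$; anything else, including ties, →
refine to midpoints $((a_0+a_1)/2,\, a_1,\, (a_1+a_2)/2)$ — ties break
toward refinement because refinement is the conservative move. A trend
that *reverses* relative to the previous round (oscillation) also
refines; the oscillation clause is scoped per hyperparameter, the
narrowest reading of an ambiguously scoped rule. Values are rounded
half-up to integers of at least 1 with collisions separated by
incrementing (stride ratios stay continuous); $K_2$ is clamped to
$2 \cdot \mathrm{NFFT} \cdot N_{fb}$ and $S_2$ to $K_2$ — "maximum value"
clamps, the reading adopted where an upper bound could otherwise be read
as either a maximum or an argmax. A triple that collapses under clamping is frozen and
reported (the collapsed stride grid $(K_2, K_2, K_2)$ is exactly what the
printed second-round tables show for the upward-trending seed set).

"Manual selection" of seed sets is operationalized as a deterministic
ranking — test accuracy, then training accuracy, then loss, then
enumeration order — with an opt-in interactive override, so the
human-in-the-loop step is reproducible in automation. The search stops
when the best test accuracy improves by less than 1 percentage point
between rounds. Within a run, evaluated combinations are memoized, so
re-enumerated combinations are never retrained. The evaluation target
(which epoch set the objective trains on) is an argument of the
objective closure, not hard-coded.

Pearson correlations of each hyperparameter with test accuracy, training
accuracy and loss are computed over all evaluated combinations; a
zero-variance column yields an explicitly flagged undefined correlation,
never a silent 0. The pairwise export min–max-normalizes test accuracy to
[0, 1].

## The CCA baseline

For window $X$ and per-target reference $Y_f$ (sines and cosines at $f$
and its harmonics, 5 by default — the convention of the filter-bank CCA
lineage; harmonics at or above Nyquist are omitted with a warning), the
largest canonical correlation is computed from the two-block covariance
eigenproblem with a ridge of $10^{-8}$ on the auto-covariance diagonals,
so rank-deficient windows (an all-zero channel, a flat-lined electrode)
classify with a warning instead of failing. The predicted target is the
argmax of $\rho$ over targets, ties toward the lowest index. The
implementation is cross-checked against a brute-force
whitening/singular-value oracle and against `stats::cancor`.

## The synthetic generator

The generator emulates the statistical structure the decoder assumes:
trial of target $k$ carries
$s_k(t) = \sum_{h=1}^{H} d^{\,h-1} \sin(2\pi h f_k t + h\phi_k)$
with $H = 3$ harmonics and decay $d = 0.5$ per harmonic (chosen to give
realistic sub-band content for filter banks up to $N_{fb} = 3$), mixed
into channels by per-channel gains drawn uniformly from
$[1 - 0.3,\ 1 + 0.3]$ (emulating electrode-gain variation without a head
model), plus noise calibrated so the per-channel signal-to-noise power
ratio equals `snr_db`. Noise is white Gaussian by default — which makes
the SNR calibration exact in expectation — with an optional 1/f ("pink")
mode. One trial per target per block, block-major order, one RNG stream
per epoch set: the seed fully determines the data.

What passing tests on this generator do show: the pipeline's bookkeeping,
spectral correctness, leakage-freedom, learnability at high SNR, and
chance-level behaviour under label shuffling. What they do not show:
performance on real EEG, which has non-stationary background rhythms,
artifacts, inter-subject variability and latency jitter that the
generator deliberately omits. The published per-subject accuracies on the
two public datasets are therefore out of scope of the test suite; the
readers for those datasets are included but import-guarded.

## Numerical and testing choices

* Problem sizes: the end-to-end benchmark trains on the full standard
  design (15 blocks × 12 targets, 10 dB SNR, 50 epochs, ≈ 4 500 training
  windows); the chance-level control uses the one-filter-bank optimized
  set; the SNR-monotonicity property uses a reduced design (4 blocks,
  15 epochs, a small one-band model); CCA exactness uses 50 random
  instances at $4\times200$ / $6\times200$.
* The search-recovery benchmark scores candidate sets with a smooth
  log-quadratic unimodal objective peaked at $(N_{k1}, N_{k2}, K_2, S_2)
  = (24, 20, 48, 12)$ inside the initial spans. Its width (scale 16 in
  squared log2 distance) is calibrated so that the *grid discretization*
  of a correct two-round search costs under 5% of the optimum, while a
  directionally wrong update rule costs tens of percent — the benchmark
  separates broken search logic from finite grid resolution.
* Dropout masks, shuffling, channel gains, noise, splits and weight
  initialization all draw from seeded streams; every reported run is a
  deterministic function of its seed.
* Containers are arrays (trials × channels × samples; feature tensors),
  not data frames — the natural shape for this signal chain — while all
  tabular results (round results, correlation tables, per-class
  accuracies) are tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Known limitations

* No online/asynchronous operation, no inter-subject transfer, no
  information-transfer-rate computation.
* The filter realization (order selection, ripple, transitions) is a
  documented convention, not a published specification; alternative
  realizations shift sub-band energies slightly.
* The `.mat` readers assume the documented array layouts of the two
  public releases and fail loudly on anything else; they require the
  optional `R.matlab` package.
* Single-threaded CPU training only; the compiled kernels are tuned for
  the desk-scale problem sizes above, not for GPU-scale search.
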