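# ssvepnet

Decoding steady-state visual evoked potentials (SSVEPs) from multi-channel
EEG. When a subject fixates a stimulus flickering at frequency *f*, the
occipital EEG carries oscillations at *f* and its harmonics; an SSVEP
brain–computer interface identifies which of *N* flickering targets the
subject is attending by classifying short EEG windows. `ssvepnet` implements
a filter-bank complex-spectrum convolutional decoder for this problem,
together with the classical canonical-correlation (CCA) baseline, a
coordinate-wise hyperparameter search, and a seeded synthetic SSVEP
generator so the whole pipeline is testable without any recordings.

## The method

Each trial (`N_ch` channels × samples) is processed as:

1. **Filter bank** — `N_fb` zero-phase Chebyshev Type I band-pass filters
   with passbands `n × 8` Hz to 88 Hz (`n = 1 … N_fb`) decompose the signal
   into sub-bands so harmonic structure is analyzed separately.
2. **Complex spectrum** — each 1 s window of each sub-band is zero-padded
   and Fourier-transformed at ≈ 0.293 Hz resolution; the real and imaginary
   parts of the `NFFT` retained bins (3–35 Hz, `NFFT = 110` at the
   defaults) are concatenated into an input matrix of size
   `N_ch × (2 · NFFT · N_fb)`.
3. **Convolutional classifier** — two convolutional layers and a dense
   output: layer 1 applies `N_k1` kernels of shape `N_ch × 1` (mixing all
   channels per frequency column), layer 2 applies `N_k2` kernels of shape
   `1 × K_2` with stride `S_2`; each convolution is followed by batch
   normalization, PReLU and dropout 0.5. The dense layer sees

   `N_f = (⌊(2·NFFT·N_fb − K_2)/S_2⌋ + 1) × N_k2`

   inputs and produces `N` class scores; training is Adam, batch 32,
   50 epochs, softmax cross-entropy, everything seeded.
4. **Hyperparameter search ("artificial gradient descent")** — each of
   `N_k1, N_k2, K_2` is searched over a `(k, 2k, 8k)` triple, the stride
   over `(K_2/8, K_2/4, K_2)`, and `N_fb` over `{1, 3, 7}`; each round
   evaluates the full 3⁵ = 243 product, classifies the marginal trend of
   each hyperparameter at the best sets, and shifts
   (`(a₂, 2a₂, 8a₂)`), refines (midpoints) or shrinks
   (`(a₀/8, a₀/2, a₀)`) its triple for the next round, with `K_2` clamped
   to the feature width and `S_2` to `K_2`.

The CCA baseline correlates each window against sine/cosine reference
templates at every stimulus frequency and its harmonics and picks the
frequency with the largest canonical correlation.

## Worked example

```r
library(ssvepnet)

# 12-target stimulus grid (9.25-14.75 Hz), 15 blocks of 4 s trials at
# 256 Hz, 10 dB per-channel SNR
layout <- make_layout("nakanishi12")
epochs <- generate_epochs(layout, fs = 256,
                          synth_config(n_blocks = 15, snr_db = 10, seed = 7))
epochs
#> <ssvep_epochs> 180 trials x 8 channels x 1024 samples @ 256 Hz, 12 targets

# classical baseline on one noiseless block
clean <- generate_epochs(layout, 256, synth_config(n_blocks = 1,
                                                   snr_db = Inf, seed = 7))
attr(cca_evaluate(clean), "accuracy")
#> [1] 100

# end-to-end decoder: 12 train / 3 test trials per class, 1 s windows,
# 0.1 s stride, 50 epochs
fit <- train_decoder(epochs, hyperparam_set(3, 64, 64, 64, 64), seed = 7)
fit$report
#> <ssvep_eval> train 100.00%  test 100.00%  loss 0.0000
```

`train 100.00%` is the training accuracy over the final epoch's windows,
`test 100.00%` the fraction of held-out 1 s windows classified correctly
(each window is one classification; at 10 dB SNR the synthetic task is
clean enough for the decoder to saturate). `glance(fit)` returns the same
numbers as a tibble, `tidy(fit)` the per-class accuracies, and
`autoplot(fit$report)` the test confusion matrix.

A thin command-line front end over the same functions is installed at
`inst/scripts/ssvepnet-cli.R` (subcommands `simulate`, `train`, `cca`,
`agd`).

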