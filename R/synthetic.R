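#' Stimulus layouts for SSVEP experiments
#'
#' An SSVEP stimulus layout is an arithmetic grid of flicker frequencies and
#' phases: target \eqn{k} (1-based) flickers at \eqn{f_0 + (k-1)\Delta f} Hz
#' with phase \eqn{\phi_0 + (k-1)\Delta\phi} radians. Two presets reproduce
#' the grids of the common public datasets: `"nakanishi12"` (12 targets,
#' 9.25--14.75 Hz in 0.5 Hz steps, phases stepping by \eqn{0.5\pi}) and
#' `"benchmark40"` (40 targets, 8--15.8 Hz in 0.2 Hz steps).
#'
#' @param preset Optional preset name, `"nakanishi12"` or `"benchmark40"`.
#'   When supplied, the explicit parameters are ignored.
#' @param n_targets Number of stimulus targets (at least 2).
#' @param f0 Base frequency in Hz.
#' @param delta_f Frequency step in Hz.
#' @param phi0 Base phase in radians.
#' @param delta_phi Phase step in radians.
#'
#' @return An object of class `ssvep_layout`: a list with fields `n_targets`,
#'   `f0`, `delta_f`, `phi0`, `delta_phi`, and derived vectors `freqs` (Hz)
#'   and `phases` (radians, reduced mod \eqn{2\pi}).
#' @examples
#' make_layout("nakanishi12")$freqs
#' make_layout(n_targets = 4, f0 = 10, delta_f = 1)$freqs
#' @export
make_layout <- function(preset = NULL, n_targets = NULL, f0 = NULL,
                        delta_f = NULL, phi0 = 0, delta_phi = 0.5 * pi) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("nakanishi12", "benchmark40"))
    par <- switch(preset,
      nakanishi12 = list(n_targets = 12L, f0 = 9.25, delta_f = 0.5,
                         phi0 = 0, delta_phi = 0.5 * pi),
      benchmark40 = list(n_targets = 40L, f0 = 8, delta_f = 0.2,
                         phi0 = 0, delta_phi = 0.5 * pi)
    )
    n_targets <- par$n_targets; f0 <- par$f0; delta_f <- par$delta_f
    phi0 <- par$phi0; delta_phi <- par$delta_phi
  } else {
    if (is.null(n_targets) || is.null(f0) || is.null(delta_f)) {
      stop("supply a `preset` or all of `n_targets`, `f0`, `delta_f`",
           call. = FALSE)
    }
    preset <- "custom"
  }
  n_targets <- as.integer(n_targets)
  if (n_targets < 2L) {
    stop("a stimulus layout needs at least 2 targets", call. = FALSE)
  }
  freqs <- f0 + (seq_len(n_targets) - 1L) * delta_f
  if (any(freqs <= 0)) {
    stop("all stimulus frequencies must be strictly positive", call. = FALSE)
  }
  phases <- (phi0 + (seq_len(n_targets) - 1L) * delta_phi) %% (2 * pi)
  structure(
    list(name = preset, n_targets = n_targets, f0 = f0, delta_f = delta_f,
         phi0 = phi0, delta_phi = delta_phi, freqs = freqs, phases = phases),
    class = "ssvep_layout"
  )
}

#' @export
print.ssvep_layout <- function(x, ...) {
  cat(sprintf("<ssvep_layout '%s'> %d targets, %.3g-%.3g Hz (step %.3g)\n",
              x$name, x$n_targets, min(x$freqs), max(x$freqs), x$delta_f))
  invisible(x)
}

#' Configuration for the synthetic SSVEP generator
#'
#' Collects the signal-model parameters used by [generate_epochs()]. The
#' evoked response to target \eqn{k} is a harmonic stack
#' \deqn{s_k(t) = \sum_{h=1}^{H} d^{\,h-1} \sin(2\pi h f_k t + h\phi_k)}
#' with decay ratio \eqn{d} per harmonic; it is mixed into channels by
#' per-channel gains and buried in noise at a prescribed per-channel SNR.
#'
#' @param n_channels Number of EEG channels.
#' @param n_harmonics Number of harmonics \eqn{H} in the evoked response
#'   (harmonics at or above Nyquist are silently dropped).
#' @param harmonic_decay Amplitude ratio between consecutive harmonics.
#' @param snr_db Per-channel signal-to-noise ratio in dB; `Inf` means
#'   noiseless.
#' @param n_blocks Number of blocks; each block holds one trial per target.
#' @param epoch_s Epoch duration in seconds.
#' @param channel_gain_spread Channel gains are drawn uniformly from
#'   `[1 - spread, 1 + spread]`.
#' @param noise `"white"` for Gaussian white noise (default; makes the SNR
#'   calibration exact in expectation) or `"pink"` for 1/f-shaped noise.
#' @param seed Integer seed; fully determines the generated epochs.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8L, n_harmonics = 3L,
                         harmonic_decay = 0.5, snr_db = Inf, n_blocks = 15L,
                         epoch_s = 4, channel_gain_spread = 0.3,
                         noise = c("white", "pink"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_channels >= 1L, n_harmonics >= 1L, harmonic_decay > 0,
            n_blocks >= 1L, epoch_s > 0, channel_gain_spread >= 0,
            channel_gain_spread < 1)
  structure(
    list(n_channels = as.integer(n_channels),
         n_harmonics = as.integer(n_harmonics),
         harmonic_decay = harmonic_decay, snr_db = snr_db,
         n_blocks = as.integer(n_blocks), epoch_s = epoch_s,
         channel_gain_spread = channel_gain_spread, noise = noise,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Construct an SSVEP epoch set
#'
#' The universal container passed between stages: a `trials x channels x
#' samples` array with per-trial labels, block indices, sampling rate and the
#' stimulus layout.
#'
#' @param data Numeric array, `trials x channels x samples`.
#' @param fs Sampling rate in Hz.
#' @param labels Integer vector of 1-based target indices, one per trial.
#' @param layout An [make_layout()] object.
#' @param block_id Integer vector of 1-based block indices, one per trial.
#' @return An object of class `ssvep_epochs`.
#' @export
ssvep_epochs <- function(data, fs, labels, layout, block_id = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L]) {
    stop("one label per trial required", call. = FALSE)
  }
  if (any(labels < 1L) || any(labels > layout$n_targets)) {
    stop("labels must index targets in the layout", call. = FALSE)
  }
  if (is.null(block_id)) block_id <- rep(1L, length(labels))
  structure(
    list(data = data, fs = fs, labels = labels, layout = layout,
         block_id = as.integer(block_id)),
    class = "ssvep_epochs"
  )
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ssvep_epochs> %d trials x %d channels x %d samples @ %g Hz, %d targets\n",
              d[1], d[2], d[3], x$fs, x$layout$n_targets))
  invisible(x)
}

# 1/f-shaped noise of length n, unit variance.
pink_noise <- function(n) {
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(1, seq_len(n - 1))           # avoid dividing the DC bin by zero
  f <- pmin(f, n - f + 1)             # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

#' Generate labelled synthetic SSVEP epochs
#'
#' Simulates stimulus-locked multi-channel EEG epochs: every trial of target
#' \eqn{k} carries the harmonic stack described in [synth_config()], scaled
#' per channel by a fixed random gain, plus noise calibrated so the
#' per-channel signal-to-noise power ratio equals `snr_db`. One trial is
#' generated per target per block, ordered block-major / target-minor, and
#' the whole epoch set is a deterministic function of the seed.
#'
#' @param layout An [make_layout()] stimulus layout.
#' @param fs Sampling rate in Hz.
#' @param cfg A [synth_config()].
#' @return An [ssvep_epochs()] object with `n_blocks * n_targets` trials.
#' @examples
#' ep <- generate_epochs(make_layout("nakanishi12"), fs = 256,
#'                       synth_config(n_blocks = 2, snr_db = 10, seed = 7))
#' ep
#' @export
generate_epochs <- function(layout, fs, cfg = synth_config()) {
  stopifnot(inherits(layout, "ssvep_layout"), inherits(cfg, "synth_config"))
  if (any(layout$freqs >= fs / 2)) {
    stop("stimulus fundamentals must lie below Nyquist (fs/2)", call. = FALSE)
  }
  n_samp <- round(fs * cfg$epoch_s)
  if (abs(n_samp - fs * cfg$epoch_s) > 1e-6) {
    stop("epoch_s * fs must be an integral number of samples", call. = FALSE)
  }
  n_trials <- cfg$n_blocks * layout$n_targets
  tt <- (seq_len(n_samp) - 1L) / fs

  # Clean per-target waveforms (shared across channels up to gain).
  sig <- matrix(0, layout$n_targets, n_samp)
  for (k in seq_len(layout$n_targets)) {
    for (h in seq_len(cfg$n_harmonics)) {
      fh <- h * layout$freqs[k]
      if (fh >= fs / 2) next
      sig[k, ] <- sig[k, ] + cfg$harmonic_decay^(h - 1) *
        sin(2 * pi * fh * tt + h * layout$phases[k])
    }
  }
  sig_pow <- rowMeans(sig^2)

  data <- array(0, dim = c(n_trials, cfg$n_channels, n_samp))
  labels <- integer(n_trials)
  blocks <- integer(n_trials)
  with_seed(cfg$seed, {
    gains <- runif(cfg$n_channels, 1 - cfg$channel_gain_spread,
                   1 + cfg$channel_gain_spread)
    i <- 0L
    for (b in seq_len(cfg$n_blocks)) {
      for (k in seq_len(layout$n_targets)) {
        i <- i + 1L
        labels[i] <- k
        blocks[i] <- b
        clean <- outer(gains, sig[k, ])
        if (is.finite(cfg$snr_db)) {
          noise_sd <- gains * sqrt(sig_pow[k] / 10^(cfg$snr_db / 10))
          noise <- if (cfg$noise == "white") {
            matrix(rnorm(cfg$n_channels * n_samp), cfg$n_channels) * noise_sd
          } else {
            t(vapply(noise_sd, function(s) s * pink_noise(n_samp),
                     numeric(n_samp)))
          }
          clean <- clean + noise
        }
        data[i, , ] <- clean
      }
    }
  })
  ep <- ssvep_epochs(data, fs, labels, layout, blocks)
  ep$gains <- gains
  ep
}
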