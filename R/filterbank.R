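#' Design a sub-band filter bank
#'
#' Builds `n_bands` band-pass Chebyshev Type I IIR filters with passbands
#' running from `n * 8` Hz to 88 Hz for band `n = 1, ..., n_bands`, the band
#' plan standard in filter-bank SSVEP analysis. Filter order is selected per
#' band from the passband ripple, stopband attenuation and transition width;
#' the stopband edges are `max(low - transition_hz, 2)` and `88 + 6` Hz.
#' Filters are applied in zero-phase (forward-backward) fashion by
#' [apply_filter_bank()].
#'
#' @param n_bands Number of sub-bands (`n_bands * 8` must be below 88 Hz).
#' @param fs Sampling rate in Hz; must exceed 2 x 88 Hz.
#' @param ripple_db Passband ripple in dB.
#' @param atten_db Stopband attenuation in dB.
#' @param transition_hz Lower transition width in Hz.
#' @return An object of class `fb_spec` with fields `n_bands`, `passbands`
#'   (list of `c(low, high)` Hz pairs), `filters` (per band: `b`, `a`
#'   coefficients and selected `order`), `fs`, and the design parameters.
#' @examples
#' spec <- design_filter_bank(3, fs = 256)
#' sapply(spec$passbands, paste, collapse = "-")
#' @export
design_filter_bank <- function(n_bands, fs, ripple_db = 3, atten_db = 40,
                               transition_hz = 4) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 1L) stop("n_bands must be positive", call. = FALSE)
  if (n_bands * 8 >= 88) {
    stop("n_bands * 8 Hz must stay below the 88 Hz band edge", call. = FALSE)
  }
  if (fs <= 2 * 88) {
    stop("fs must exceed 176 Hz so the 88 Hz band edge is below Nyquist",
         call. = FALSE)
  }
  nyq <- fs / 2
  stop_hi <- min(88 + 6, 88 + 0.5 * (nyq - 88))
  bands <- lapply(seq_len(n_bands), function(n) c(n * 8, 88))
  filters <- lapply(bands, function(pb) {
    stop_lo <- max(pb[1] - transition_hz, 2)
    ord <- signal::cheb1ord(Wp = pb / nyq, Ws = c(stop_lo, stop_hi) / nyq,
                            Rp = ripple_db, Rs = atten_db)
    fl <- signal::cheby1(ord)
    roots <- Mod(polyroot(rev(fl$a)))
    if (any(roots >= 1)) {
      stop(sprintf("designed filter for band %g-%g Hz is unstable",
                   pb[1], pb[2]), call. = FALSE)
    }
    list(b = fl$b, a = fl$a, order = ord$n)
  })
  structure(
    list(n_bands = n_bands, passbands = bands, filters = filters, fs = fs,
         ripple_db = ripple_db, atten_db = atten_db,
         transition_hz = transition_hz),
    class = "fb_spec"
  )
}

#' @export
print.fb_spec <- function(x, ...) {
  cat(sprintf("<fb_spec> %d band(s) @ %g Hz: %s\n", x$n_bands, x$fs,
              paste(vapply(x$passbands, function(p)
                sprintf("[%g,%g]", p[1], p[2]), ""), collapse = " ")))
  invisible(x)
}

# One causal IIR pass with steady-state (DC-matched) initial conditions, so
# the startup transient of a constant input is zero.
iir_pass <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1L),
                            init.y = rep(x[1] * dc, length(a) - 1L)))
}

#' Zero-phase filtering of a single series
#'
#' Forward-backward application of an IIR filter with odd-symmetric edge
#' padding of length `3 x (filter order)` and steady-state initial
#' conditions, the standard zero-phase contract: the magnitude response is
#' squared and the phase response cancels.
#'
#' @param b,a Filter numerator/denominator coefficients.
#' @param x Numeric series; must be longer than the padding.
#' @param padlen Edge padding length in samples.
#' @return Filtered series of the same length as `x`.
#' @export
filtfilt_zerophase <- function(b, a, x,
                               padlen = 3L * (max(length(a), length(b)) - 1L)) {
  n <- length(x)
  if (n <= padlen) {
    stop(sprintf("series of %d samples is shorter than the filter warm-up (%d)",
                 n, padlen + 1L), call. = FALSE)
  }
  front <- 2 * x[1] - x[(padlen + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xp <- c(front, x, back)
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Decompose epochs into sub-band components
#'
#' Applies every band of a filter bank to every channel of every trial in
#' zero-phase fashion, returning one epoch set per sub-band with unchanged
#' shape, labels and layout.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param spec A [design_filter_bank()] specification with matching `fs`.
#' @return A list of `ssvep_epochs`, one per band in ascending band order;
#'   each carries its band index in `$band`.
#' @export
apply_filter_bank <- function(epochs, spec) {
  stopifnot(inherits(epochs, "ssvep_epochs"), inherits(spec, "fb_spec"))
  if (!isTRUE(all.equal(epochs$fs, spec$fs))) {
    stop("sampling rate of epochs and filter bank differ", call. = FALSE)
  }
  d <- dim(epochs$data)
  lapply(seq_len(spec$n_bands), function(bi) {
    fl <- spec$filters[[bi]]
    out <- epochs$data
    for (tr in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        out[tr, ch, ] <- filtfilt_zerophase(fl$b, fl$a, epochs$data[tr, ch, ])
      }
    }
    ep <- ssvep_epochs(out, epochs$fs, epochs$labels, epochs$layout,
                       epochs$block_id)
    ep$trial_id <- epochs$trial_id
    ep$band <- bi
    ep
  })
}
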