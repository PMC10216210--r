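#' Define the complex-spectrum feature grid
#'
#' Fixes the FFT length and the retained frequency bins used to build
#' complex-spectrum features. The FFT length is the smallest that reaches
#' the requested frequency resolution, `ceiling(fs / resolution)`, and the
#' retained bins are those whose centre is nearest the requested band edges:
#' bins `round(f_lo / df) .. round(f_hi / df)` at the realized resolution
#' `df = fs / fft_length`. At the defaults (`resolution = 0.293` Hz, band
#' 3-35 Hz, fs 256) this yields an FFT length of 874 and `n_bins = 110`
#' retained components per channel per band.
#'
#' @param fs Sampling rate in Hz.
#' @param resolution Target FFT frequency resolution in Hz.
#' @param band Length-2 numeric, retained band `c(f_lo, f_hi)` in Hz.
#' @return An object of class `spectrum_spec` with fields `fs`, `resolution`,
#'   `band`, `fft_length`, `bin_index` (0-based DFT bin indices), `freqs`
#'   (bin centre frequencies, Hz) and `n_bins`.
#' @examples
#' make_spectrum_spec(256)$n_bins
#' @export
make_spectrum_spec <- function(fs, resolution = 0.293, band = c(3, 35)) {
  stopifnot(fs > 0, resolution > 0, length(band) == 2)
  if (!(band[1] > 0 && band[1] <= band[2] && band[2] <= fs / 2)) {
    stop("band must satisfy 0 < f_lo <= f_hi <= fs/2", call. = FALSE)
  }
  fft_length <- as.integer(ceiling(fs / resolution))
  df <- fs / fft_length
  k_lo <- round_half_up(band[1] / df)
  k_hi <- round_half_up(band[2] / df)
  if (k_hi < k_lo) stop("band contains no FFT bins", call. = FALSE)
  bin_index <- as.integer(k_lo:k_hi)
  structure(
    list(fs = fs, resolution = resolution, band = band,
         fft_length = fft_length, bin_index = bin_index,
         freqs = bin_index * df, n_bins = length(bin_index)),
    class = "spectrum_spec"
  )
}

#' @export
print.spectrum_spec <- function(x, ...) {
  cat(sprintf("<spectrum_spec> fft_length %d (res %.4g Hz), %d bins in [%g, %g] Hz\n",
              x$fft_length, x$fs / x$fft_length, x$n_bins,
              x$band[1], x$band[2]))
  invisible(x)
}

# Real/imaginary DFT matrices restricted to the retained bins, applied to
# zero-padded windows by plain matrix multiplication (exact, no taper).
dft_matrices <- function(spec, n_samples) {
  ang <- -2 * pi * outer(spec$bin_index, 0:(n_samples - 1L)) / spec$fft_length
  list(re = cos(ang), im = sin(ang))
}

#' Complex-spectrum features of one window
#'
#' Computes the discrete Fourier transform of each channel of a window
#' (zero-padded to the spec's FFT length, rectangular window) at the
#' retained bins and returns real parts followed by imaginary parts, each
#' `n_bins` wide: a `channels x (2 * n_bins)` block.
#'
#' @param window Numeric matrix, `channels x samples`.
#' @param spec A [make_spectrum_spec()] object.
#' @return Numeric matrix `channels x (2 * n_bins)`.
#' @export
complex_spectrum <- function(window, spec) {
  stopifnot(is.matrix(window), inherits(spec, "spectrum_spec"))
  ns <- ncol(window)
  if (ns > spec$fft_length) {
    stop("window longer than the FFT length", call. = FALSE)
  }
  E <- dft_matrices(spec, ns)
  cbind(tcrossprod(window, E$re), tcrossprod(window, E$im))
}

#' Assemble filter-bank complex-spectrum features
#'
#' Turns band-wise windowed epochs into the network input: for each window,
#' the per-band `channels x (2 * n_bins)` complex-spectrum blocks are
#' concatenated in ascending band order into a `channels x (2 * n_bins *
#' n_bands)` matrix. A layout descriptor records, for every column, its band
#' index, real/imaginary part and bin frequency.
#'
#' @param band_windows A list of windowed epoch sets as returned by
#'   [segment_epochs()] applied to each band of [apply_filter_bank()] (or a
#'   single windowed set for one band). All bands must share window shape,
#'   labels and ordering.
#' @param spec A [make_spectrum_spec()] object.
#' @return An object of class `ssvep_features`: list with `x` (array
#'   `channels x width x n_windows`), `labels`, `trial` (source trial ids),
#'   `block_id`, `columns` (tibble: `column`, `band`, `part`, `freq_hz`),
#'   `n_bins`, `n_bands`, `n_channels`, `layout`.
#' @export
assemble_features <- function(band_windows, spec) {
  if (inherits(band_windows, "ssvep_windows")) {
    band_windows <- list(band_windows)
  }
  stopifnot(length(band_windows) >= 1L, inherits(spec, "spectrum_spec"))
  bands <- vapply(band_windows, function(w) as.integer(w$band %||% 1L), 1L)
  if (!identical(bands, sort(bands)) || anyDuplicated(bands)) {
    stop("band windows must be supplied in ascending band order", call. = FALSE)
  }
  d1 <- dim(band_windows[[1]]$data)
  lab <- band_windows[[1]]$labels
  for (w in band_windows[-1]) {
    if (!identical(dim(w$data), d1) || !identical(w$labels, lab)) {
      stop("all bands must share window shape and labels", call. = FALSE)
    }
  }
  n_win <- d1[1]; n_ch <- d1[2]; n_samp <- d1[3]
  if (n_samp > spec$fft_length) {
    stop("window longer than the FFT length", call. = FALSE)
  }
  E <- dft_matrices(spec, n_samp)
  nb <- spec$n_bins
  width <- 2L * nb * length(band_windows)
  x <- array(0, dim = c(n_ch, width, n_win))
  for (bi in seq_along(band_windows)) {
    # All windows x channels at once: samples x (n_win * n_ch) matrix.
    flat <- matrix(aperm(band_windows[[bi]]$data, c(3, 1, 2)), nrow = n_samp)
    re <- E$re %*% flat   # n_bins x (n_win * n_ch)
    im <- E$im %*% flat
    off <- (bi - 1L) * 2L * nb
    for (ch in seq_len(n_ch)) {
      cols <- (ch - 1L) * n_win + seq_len(n_win)
      x[ch, off + seq_len(nb), ] <- re[, cols]
      x[ch, off + nb + seq_len(nb), ] <- im[, cols]
    }
  }
  columns <- tibble::tibble(
    column = seq_len(width),
    band = rep(bands, each = 2L * nb),
    part = rep(rep(c("re", "im"), each = nb), times = length(band_windows)),
    freq_hz = rep(rep(spec$freqs, 2L), times = length(band_windows))
  )
  structure(
    list(x = x, labels = lab, trial = band_windows[[1]]$trial,
         block_id = band_windows[[1]]$block_id, columns = columns,
         n_bins = nb, n_bands = length(band_windows), n_channels = n_ch,
         layout = band_windows[[1]]$layout),
    class = "ssvep_features"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ssvep_features <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<ssvep_features> %d windows of %d x %d (%d band(s), %d bins)\n",
              d[3], d[1], d[2], x$n_bands, x$n_bins))
  invisible(x)
}
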