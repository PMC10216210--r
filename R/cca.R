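#' Sinusoidal reference templates for CCA
#'
#' For each stimulus frequency builds the classical reference matrix of sine
#' and cosine waves at the fundamental and its harmonics, rows ordered
#' `(sin h=1, cos h=1, sin h=2, cos h=2, ...)`. Harmonics at or above
#' Nyquist are omitted with a warning.
#'
#' @param layout An [make_layout()] stimulus layout.
#' @param fs Sampling rate in Hz.
#' @param n_samples Template length in samples.
#' @param n_harmonics Number of harmonics per target (default 5, the
#'   convention of the filter-bank CCA lineage).
#' @return List of class `cca_templates`: per target a `2*Nh x n_samples`
#'   matrix, plus `fs` and `layout`.
#' @export
cca_templates <- function(layout, fs, n_samples, n_harmonics = 5L) {
  stopifnot(inherits(layout, "ssvep_layout"), n_samples >= 2, n_harmonics >= 1)
  tt <- (seq_len(n_samples) - 1L) / fs
  dropped <- FALSE
  Y <- lapply(layout$freqs, function(f) {
    rows <- list()
    for (h in seq_len(n_harmonics)) {
      if (h * f >= fs / 2) { dropped <<- TRUE; next }
      rows[[length(rows) + 1L]] <- sin(2 * pi * h * f * tt)
      rows[[length(rows) + 1L]] <- cos(2 * pi * h * f * tt)
    }
    if (!length(rows)) {
      stop(sprintf("no harmonics of %g Hz below Nyquist", f), call. = FALSE)
    }
    do.call(rbind, rows)
  })
  if (dropped) {
    warning("harmonics at or above Nyquist were omitted from the templates",
            call. = FALSE)
  }
  structure(list(Y = Y, fs = fs, layout = layout,
                 n_harmonics = as.integer(n_harmonics)),
            class = "cca_templates")
}

#' Largest canonical correlation between two multivariate signals
#'
#' Computes the maximal canonical correlation
#' \deqn{\rho(X, Y) = \max_{w_x, w_y}
#'   \frac{w_x^\top C_{xy} w_y}{\sqrt{w_x^\top C_{xx} w_x}\,
#'   \sqrt{w_y^\top C_{yy} w_y}}}
#' by solving the two-block generalized eigenproblem on the (internally
#' centred) covariances. A ridge `reg` is added to the auto-covariance
#' diagonals; rank-deficient inputs therefore return a finite value with a
#' warning instead of failing.
#'
#' @param X Numeric matrix `Nx x Ns` (variables in rows).
#' @param Y Numeric matrix `Ny x Ns`.
#' @param reg Diagonal regularization added to the auto-covariances.
#' @return Numeric scalar in `[0, 1]`, with attributes `wx` and `wy`, the
#'   canonical weight vectors.
#' @examples
#' t <- seq(0, 1, length.out = 200)
#' X <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
#' canonical_correlation(X, X)
#' @export
canonical_correlation <- function(X, Y, reg = 1e-8) {
  stopifnot(is.matrix(X), is.matrix(Y), ncol(X) == ncol(Y))
  ns <- ncol(X)
  if (ns <= max(nrow(X), nrow(Y))) {
    stop("need more samples than variables", call. = FALSE)
  }
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / ns
  Cyy <- tcrossprod(Yc) / ns
  Cxy <- tcrossprod(Xc, Yc) / ns
  if (min(diag(Cxx)) < reg || min(diag(Cyy)) < reg) {
    warning("near-degenerate input; regularized canonical correlation",
            call. = FALSE)
  }
  diag(Cxx) <- diag(Cxx) + reg
  diag(Cyy) <- diag(Cyy) + reg
  # rho^2 = largest eigenvalue of Cxx^-1 Cxy Cyy^-1 Cyx.
  A <- solve(Cxx, Cxy %*% solve(Cyy, t(Cxy)))
  ei <- eigen(A)
  vals <- Re(ei$values)
  i <- which.max(vals)
  rho <- sqrt(max(min(vals[i], 1), 0))
  wx <- Re(ei$vectors[, i])
  wy <- solve(Cyy, t(Cxy) %*% wx)
  nx <- sqrt(sum(wx * (Cxx %*% wx)))
  ny <- sqrt(sum(wy * (Cyy %*% wy)))
  if (nx > 0) wx <- wx / nx
  if (ny > 0) wy <- wy / ny
  structure(rho, wx = as.numeric(wx), wy = as.numeric(wy))
}

#' Classify one window by canonical correlation
#'
#' Correlates a window against every target's sinusoidal reference and
#' returns the target with the largest canonical correlation (ties broken
#' toward the lowest target index).
#'
#' @param window Numeric matrix `channels x samples`.
#' @param templates A [cca_templates()] object with matching sample count.
#' @return Integer 1-based target index; attribute `rho` holds the
#'   per-target correlations.
#' @export
cca_classify <- function(window, templates) {
  stopifnot(is.matrix(window), inherits(templates, "cca_templates"))
  if (ncol(window) != ncol(templates$Y[[1]])) {
    stop("window length does not match the templates", call. = FALSE)
  }
  rho <- vapply(templates$Y, function(Y)
    as.numeric(canonical_correlation(window, Y)), 0)
  structure(which.max(rho), rho = rho)
}

#' Window-level CCA evaluation of an epoch set
#'
#' The classical baseline protocol: trials are segmented into windows and
#' every window is classified independently with [cca_classify()].
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param n_harmonics Harmonics per reference template.
#' @param window_s,stride_s Windowing, see [segment_epochs()].
#' @return A tibble with one row per window: `trial`, `label`, `predicted`,
#'   `correct`; attribute `accuracy` gives the percent correct.
#' @export
cca_evaluate <- function(epochs, n_harmonics = 5L, window_s = 1,
                         stride_s = 0.1) {
  wins <- segment_epochs(epochs, window_s, stride_s)
  n_samp <- dim(wins$data)[3]
  templates <- cca_templates(epochs$layout, epochs$fs, n_samp, n_harmonics)
  n <- dim(wins$data)[1]
  pred <- integer(n)
  for (i in seq_len(n)) {
    w <- wins$data[i, , , drop = FALSE]
    dim(w) <- dim(w)[2:3]
    pred[i] <- cca_classify(w, templates)
  }
  out <- tibble::tibble(trial = wins$trial, label = wins$labels,
                        predicted = pred, correct = pred == wins$labels)
  attr(out, "accuracy") <- 100 * mean(out$correct)
  out
}
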