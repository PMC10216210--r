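# Shared fixtures, generated in code and memoized for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# 2 blocks of clean-ish 12-target epochs at the standard rate.
tiny_epochs <- function(snr_db = 10, n_blocks = 2, seed = 7) {
  fixture(sprintf("ep_%s_%d_%d", snr_db, n_blocks, seed),
          generate_epochs(make_layout("nakanishi12"), 256,
                          synth_config(n_blocks = n_blocks, snr_db = snr_db,
                                       seed = seed)))
}

tiny_features <- function() {
  fixture("feats", {
    ep <- tiny_epochs()
    extract_features(ep, design_filter_bank(3, 256), make_spectrum_spec(256))
  })
}

# Naive O(N^2) DFT at the retained bins: the independent spectrum oracle.
dft_oracle <- function(x, spec) {
  n <- length(x)
  vapply(spec$bin_index, function(k) {
    ang <- -2 * pi * k * (0:(n - 1)) / spec$fft_length
    complex(real = sum(x * cos(ang)), imaginary = sum(x * sin(ang)))
  }, complex(1))
}

# Brute-force canonical-correlation oracle: whiten both blocks with
# eigendecompositions and take the largest singular value of the
# cross-correlation of the whitened variables.
cca_oracle <- function(X, Y) {
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  n <- ncol(X)
  Cxx <- tcrossprod(Xc) / n; Cyy <- tcrossprod(Yc) / n
  Cxy <- tcrossprod(Xc, Yc) / n
  whiten <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
      t(e$vectors)
  }
  max(svd(whiten(Cxx) %*% Cxy %*% whiten(Cyy))$d)
}
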