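test_that("spectrum spec derives the FFT grid from the target resolution", {
  sp <- make_spectrum_spec(256, 0.293, c(3, 35))
  expect_equal(sp$fft_length, 874L)
  expect_lte(256 / sp$fft_length, 0.293)
  expect_equal(sp$n_bins, 110L)
  expect_true(all(diff(sp$bin_index) == 1))

  # a band holding exactly one bin
  sp1 <- make_spectrum_spec(256, 1, c(10, 10))
  expect_equal(sp1$n_bins, 1L)
  expect_error(make_spectrum_spec(256, 0.293, c(40, 35)), "f_lo")
})

test_that("complex spectrum matches a naive DFT-sum oracle", {
  sp <- make_spectrum_spec(256)
  set.seed(42)
  for (rep in 1:5) {
    w <- matrix(rnorm(3 * 256), 3, 256)
    got <- complex_spectrum(w, sp)
    for (ch in 1:3) {
      ref <- dft_oracle(w[ch, ], sp)
      expect_lt(max(abs(got[ch, 1:110] - Re(ref))) / max(abs(ref)), 1e-9)
      expect_lt(max(abs(got[ch, 111:220] - Im(ref))) / max(abs(ref)), 1e-9)
    }
  }
})

test_that("a tone on a retained bin peaks exactly there", {
  sp <- make_spectrum_spec(256)
  k <- sp$bin_index[50]
  f <- k * 256 / sp$fft_length
  w <- matrix(sin(2 * pi * f * (0:873) / 256), 1)[, 1:256, drop = FALSE]
  feat <- complex_spectrum(w, sp)
  mag <- sqrt(feat[1, 1:110]^2 + feat[1, 111:220]^2)
  expect_equal(which.max(mag), 50L)
  expect_error(complex_spectrum(matrix(0, 1, 1000), sp), "longer")
  expect_true(all(complex_spectrum(matrix(0, 2, 256), sp) == 0))
})

test_that("feature assembly concatenates bands in order with full metadata", {
  feats <- tiny_features()
  expect_equal(dim(feats$x)[2], 2 * 110 * 3)
  expect_equal(dim(feats$x)[1], 8)

  cols <- feats$columns
  expect_equal(nrow(cols), 660L)
  expect_equal(unique(cols$band), 1:3)
  # per band: 110 re columns then 110 im columns
  expect_equal(cols$part[1:220], rep(c("re", "im"), each = 110))
  expect_equal(cols$freq_hz[1:110], make_spectrum_spec(256)$freqs)
  # layout descriptor reconstructs every column uniquely
  expect_equal(anyDuplicated(cols[, c("band", "part", "freq_hz")]), 0L)
})

test_that("single-band assembly is the band's own block; order is enforced", {
  ep <- tiny_epochs()
  sp <- make_spectrum_spec(256)
  bands <- apply_filter_bank(ep, design_filter_bank(3, 256))
  wins <- lapply(bands, segment_epochs)
  one <- assemble_features(wins[[1]], sp)
  expect_equal(dim(one$x)[2], 220)
  both <- assemble_features(wins, sp)
  expect_equal(both$x[, 1:220, 1], one$x[, , 1])
  expect_error(assemble_features(wins[c(2, 1, 3)], sp), "ascending")
})

test_that("column count follows 2 * n_bins * n_bands", {
  ep <- tiny_epochs()
  sp <- make_spectrum_spec(256)
  for (nfb in c(1L, 3L, 7L)) {
    fs_use <- if (nfb == 7L) 250 else 256
    ep_use <- if (nfb == 7L) {
      generate_epochs(make_layout("nakanishi12"), 250,
                      synth_config(n_blocks = 1, snr_db = 10, seed = 1,
                                   epoch_s = 2))
    } else {
      ep
    }
    sp_use <- make_spectrum_spec(fs_use)
    wins <- lapply(apply_filter_bank(ep_use, design_filter_bank(nfb, fs_use)),
                   segment_epochs)
    feats <- assemble_features(wins, sp_use)
    expect_equal(dim(feats$x)[2], 2L * sp_use$n_bins * nfb)
  }
})

test_that("transform is linear and satisfies Parseval on the full grid", {
  sp <- make_spectrum_spec(256)
  set.seed(9)
  x <- matrix(rnorm(256), 1); y <- matrix(rnorm(256), 1)
  lhs <- complex_spectrum(2 * x - 3 * y, sp)
  rhs <- 2 * complex_spectrum(x, sp) - 3 * complex_spectrum(y, sp)
  expect_lt(max(abs(lhs - rhs)), 1e-9)

  # Parseval on the unrestricted transform of the zero-padded window
  xp <- c(x[1, ], rep(0, sp$fft_length - 256))
  X <- fft(xp)
  expect_equal(sum(Mod(X)^2), sp$fft_length * sum(xp^2), tolerance = 1e-10)
})
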