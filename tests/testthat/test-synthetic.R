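test_that("layout presets reproduce the standard stimulus grids", {
  lay <- make_layout("nakanishi12")
  expect_equal(lay$n_targets, 12L)
  expect_equal(lay$freqs, seq(9.25, 14.75, by = 0.5))
  expect_equal(lay$phases, (0.5 * pi * 0:11) %% (2 * pi))

  lay40 <- make_layout("benchmark40")
  expect_equal(lay40$n_targets, 40L)
  expect_equal(lay40$freqs, seq(8, 15.8, by = 0.2))
})

test_that("degenerate or invalid layouts are rejected", {
  expect_error(make_layout(n_targets = 1, f0 = 10, delta_f = 1),
               "at least 2 targets")
  expect_error(make_layout(n_targets = 3, f0 = -1, delta_f = 0.1),
               "strictly positive")
  expect_error(make_layout("nope"))
})

test_that("trial bookkeeping matches the block/target design", {
  ep <- generate_epochs(make_layout("nakanishi12"), 256,
                        synth_config(n_blocks = 15, snr_db = 0, seed = 3,
                                     epoch_s = 1))
  expect_equal(dim(ep$data), c(180, 8, 256))
  expect_equal(as.vector(table(ep$labels)), rep(15L, 12))
  expect_equal(ep$labels[1:12], 1:12)     # target-minor within a block
  expect_equal(unique(ep$block_id[1:12]), 1L)
})

test_that("identical configuration gives bit-identical epochs", {
  cfg <- synth_config(n_blocks = 2, snr_db = 5, seed = 11, epoch_s = 1)
  a <- generate_epochs(make_layout("nakanishi12"), 256, cfg)
  b <- generate_epochs(make_layout("nakanishi12"), 256, cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
})

test_that("periodogram peak sits at the stimulus fundamental", {
  # noiseless single-target check at 9.25 Hz, 4 s, fs = 256
  ep <- generate_epochs(make_layout("nakanishi12"), 256,
                        synth_config(n_blocks = 1, snr_db = Inf, seed = 1))
  tr <- which(ep$labels == 1)
  f_axis <- (0:511) * 256 / 1024
  for (ch in 1:8) {
    pg <- abs(fft(ep$data[tr, ch, ]))[1:512]
    expect_lt(abs(f_axis[which.max(pg)] - 9.25), 256 / 1024 + 1e-9)
  }

  # at 20 dB SNR, >= 95% of trials peak within one bin of their fundamental
  ep2 <- generate_epochs(make_layout("nakanishi12"), 256,
                         synth_config(n_blocks = 5, snr_db = 20, seed = 2))
  hit <- vapply(seq_along(ep2$labels), function(i) {
    f_true <- ep2$layout$freqs[ep2$labels[i]]
    pg <- abs(fft(ep2$data[i, 1, ]))[1:512]
    abs(f_axis[which.max(pg)] - f_true) <= 256 / 1024 + 1e-9
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("empirical SNR matches the requested level within 1 dB", {
  for (noise in c("white", "pink")) {
    cfg <- synth_config(n_blocks = 5, snr_db = 0, seed = 4, epoch_s = 1,
                        noise = noise)
    lay <- make_layout("nakanishi12")
    ep <- generate_epochs(lay, 256, cfg)          # 60 trials
    clean <- generate_epochs(lay, 256,
                             synth_config(n_blocks = 5, snr_db = Inf,
                                          seed = 4, epoch_s = 1))
    noise_part <- ep$data - clean$data
    snr_emp <- 10 * log10(mean(clean$data^2) / mean(noise_part^2))
    expect_lt(abs(snr_emp - 0), 1)
  }
})

test_that("harmonics above Nyquist are dropped, fundamentals above fail", {
  lay <- make_layout(n_targets = 2, f0 = 100, delta_f = 5)   # 2nd harmonic > 128
  ep <- generate_epochs(lay, 256, synth_config(n_blocks = 1, snr_db = Inf,
                                               seed = 1, epoch_s = 1))
  # spectrum content only at the fundamental
  pg <- abs(fft(ep$data[1, 1, ]))[1:128]
  expect_lt(abs(which.max(pg) - 1 - 100), 1.5)
  lay_bad <- make_layout(n_targets = 2, f0 = 127, delta_f = 5)
  expect_error(generate_epochs(lay_bad, 256, synth_config(n_blocks = 1)),
               "Nyquist")
})
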