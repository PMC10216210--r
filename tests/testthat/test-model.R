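test_that("flatten width follows the conv-2 sliding-window count", {
  expect_equal(flatten_width(hyperparam_set(3, 64, 64, 64, 64), 110), 640L)
  expect_equal(flatten_width(hyperparam_set(1, 64, 16, 64, 8), 110), 320L)
  # a full-width kernel leaves a single output position
  expect_equal(flatten_width(hyperparam_set(1, 4, 7, 220, 11), 110), 7L)
  expect_error(flatten_width(hyperparam_set(1, 4, 4, 300, 8), 110),
               "exceeds")
  expect_error(hyperparam_set(1, 4, 4, 16, 32), "stride")
  expect_error(hyperparam_set(0, 4, 4, 16, 8), "positive")
})

test_that("flatten width is non-increasing in stride and kernel width", {
  base <- c(nfb = 1L, nk1 = 8L, nk2 = 8L)
  widths_s <- vapply(c(2, 4, 8, 16, 32), function(s2)
    flatten_width(hyperparam_set(1, 8, 8, 32, s2), 110), 1L)
  expect_true(all(diff(widths_s) <= 0))
  widths_k <- vapply(c(16, 32, 64, 128), function(k2)
    flatten_width(hyperparam_set(1, 8, 8, k2, 16), 110), 1L)
  expect_true(all(diff(widths_k) <= 0))
})

test_that("channel-number-based sets reproduce the printed conventions", {
  hp3 <- channel_based_hyperparams(8, "three_band")
  expect_equal(unlist(hp3[c("nfb", "nk1", "nk2", "k2", "s2")]),
               c(nfb = 3L, nk1 = 64L, nk2 = 64L, k2 = 64L, s2 = 64L))
  expect_false(attr(hp3, "clamped"))

  hp64 <- channel_based_hyperparams(64, "three_band")
  expect_equal(unlist(hp64[c("nk1", "nk2", "k2", "s2")]),
               c(nk1 = 512L, nk2 = 512L, k2 = 512L, s2 = 512L))

  hp1 <- channel_based_hyperparams(1, "one_band")
  expect_equal(unlist(hp1[c("nfb", "nk1", "nk2", "k2", "s2")]),
               c(nfb = 1L, nk1 = 8L, nk2 = 2L, k2 = 8L, s2 = 1L))

  # one-band at 64 channels exceeds the 220-wide feature map: k2 clamps
  expect_warning(hp_cl <- channel_based_hyperparams(64, "one_band"),
                 "clamped")
  expect_equal(hp_cl$k2, 220L)
  expect_true(attr(hp_cl, "clamped"))
})

test_that("realized flatten width agrees with the formula on random sets", {
  set.seed(123)
  for (i in 1:100) {
    n_bins <- sample(20:60, 1)
    nfb <- sample(c(1L, 2L, 3L), 1)
    width <- 2L * n_bins * nfb
    k2 <- sample(2:width, 1)
    s2 <- sample(seq_len(k2), 1)
    hp <- hyperparam_set(nfb, sample(2:16, 1), sample(2:16, 1), k2, s2)
    # oracle: enumerate the sliding-window positions explicitly
    n_pos <- 0L
    t <- 0L
    while (t + k2 <= width) {
      n_pos <- n_pos + 1L
      t <- t + s2
    }
    expect_identical(flatten_width(hp, n_bins), n_pos * hp$nk2)
    m <- build_model(hp, n_channels = 4, n_bins = n_bins, n_classes = 5,
                     seed = i)
    expect_identical(m$n_flat, n_pos * hp$nk2)
  }
})

test_that("the printed optimized set builds and predicts with right shapes", {
  m <- build_model(hyperparam_set(3, 64, 64, 64, 64), 8, 110, 12, seed = 1)
  expect_equal(m$n_flat, 640L)
  feats <- tiny_features()
  sc <- predict(m, feats, type = "score")
  expect_equal(dim(sc), c(dim(feats$x)[3], 12L))
  pr <- predict(m, feats, type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12)
  expect_error(build_model(hyperparam_set(3, 4, 4, 64, 64), 8, 5, 12),
               "exceeds")
})

test_that("compiled and reference forward/backward passes agree", {
  m <- build_model(hyperparam_set(2, 12, 10, 24, 8), 4, 30, 6, seed = 2)
  m$dropout <- 0
  set.seed(77)
  x <- array(rnorm(4 * m$width * 16), dim = c(4, m$width, 16))
  y <- rep(1:4, 4)

  fwR <- ssvepnet:::fbccnn_forward(m, x, training = FALSE)
  fwC <- ssvepnet:::fbccnn_batch(m, x, training = FALSE)
  expect_equal(fwC$scores, fwR$scores, tolerance = 1e-12)

  fwRt <- ssvepnet:::fbccnn_forward(m, x, training = TRUE, keep = TRUE)
  Y <- matrix(0, 6, 16); Y[cbind(y, 1:16)] <- 1
  grR <- ssvepnet:::fbccnn_backward(m, fwRt, Y)
  stC <- ssvepnet:::fbccnn_batch(m, x, training = TRUE, y = y)
  for (nm in names(grR)) {
    expect_equal(as.numeric(stC$grads[[nm]]), as.numeric(grR[[nm]]),
                 tolerance = 1e-9, label = nm)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  m <- build_model(hyperparam_set(1, 3, 3, 6, 3), 2, 8, 3, seed = 5)
  m$dropout <- 0
  set.seed(8)
  x <- array(rnorm(2 * m$width * 4), dim = c(2, m$width, 4))
  y <- c(1L, 2L, 3L, 1L)
  loss_at <- function(model) {
    st <- ssvepnet:::fbccnn_batch(model, x, training = TRUE, y = y)
    st$loss / 4
  }
  st <- ssvepnet:::fbccnn_batch(m, x, training = TRUE, y = y)
  eps <- 1e-6
  for (nm in c("W1", "g1", "a1", "W2", "be2", "W3", "b3")) {
    p <- m$params[[nm]]
    i <- if (length(p) > 1) 2 else 1
    mp <- m; mp$params[[nm]][i] <- p[i] + eps
    mm <- m; mm$params[[nm]][i] <- p[i] - eps
    fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    an <- as.numeric(st$grads[[nm]])[i]
    expect_equal(an, fd, tolerance = 1e-4, label = nm)
  }
})

test_that("inference is deterministic and batch-size invariant", {
  m <- build_model(hyperparam_set(1, 8, 8, 16, 8), 4, 20, 5, seed = 3)
  set.seed(1)
  x <- array(rnorm(4 * m$width * 10), dim = c(4, m$width, 10))
  s1 <- predict(m, x, type = "score")
  s2 <- predict(m, x, type = "score")
  expect_identical(s1, s2)
  one_by_one <- t(vapply(1:10, function(i)
    predict(m, x[, , i, drop = FALSE], type = "score")[1, ], numeric(5)))
  expect_equal(one_by_one, s1, tolerance = 1e-10)
})
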