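test_that("window segmentation counts match explicit enumeration", {
  ep <- tiny_epochs()                       # 4 s epochs at 256 Hz
  wins <- segment_epochs(ep, window_s = 1, stride_s = 0.1)
  # oracle: enumerate start samples at round(k * 25.6) while windows fit
  starts <- round((0:100) * 0.1 * 256)
  n_fit <- sum(starts + 256 <= 1024)
  expect_equal(wins$n_per_trial, n_fit)
  expect_equal(wins$n_per_trial, 31L)
  expect_equal(dim(wins$data), c(31L * 24L, 8L, 256L))
  expect_equal(wins$labels[1:31], rep(ep$labels[1], 31))

  # window equal to the epoch: exactly one window
  one <- segment_epochs(ep, window_s = 4, stride_s = 0.1)
  expect_equal(one$n_per_trial, 1L)
  expect_equal(one$data[1, , ], ep$data[1, , ])

  short <- generate_epochs(make_layout("nakanishi12"), 256,
                           synth_config(n_blocks = 1, epoch_s = 0.5,
                                        snr_db = Inf, seed = 1))
  expect_error(segment_epochs(short, window_s = 1), "longer than the epoch")
})

test_that("trial-level split is stratified, disjoint and seeded", {
  ep <- generate_epochs(make_layout("nakanishi12"), 256,
                        synth_config(n_blocks = 15, snr_db = 0, seed = 5,
                                     epoch_s = 1))
  sp <- split_by_trials(ep, 3, seed = 2)
  expect_equal(as.vector(table(sp$train$labels)), rep(12L, 12))
  expect_equal(as.vector(table(sp$test$labels)), rep(3L, 12))
  expect_length(intersect(sp$train$trial_id, sp$test$trial_id), 0L)

  sp2 <- split_by_trials(ep, 3, seed = 2)
  expect_identical(sp$test$trial_id, sp2$test$trial_id)

  all_train <- split_by_trials(ep, 0, seed = 1)
  expect_equal(length(all_train$train$labels), 180L)
  expect_equal(length(all_train$test$labels), 0L)
  expect_error(split_by_trials(ep, 15, seed = 1), "fewer")
})

test_that("no window leaks across the trial-level split", {
  ep <- tiny_epochs()
  sp <- split_by_trials(ep, 1, seed = 3)
  fb <- design_filter_bank(1, 256)
  spx <- make_spectrum_spec(256)
  tr <- extract_features(sp$train, fb, spx)
  te <- extract_features(sp$test, fb, spx)
  expect_length(intersect(unique(tr$trial), unique(te$trial)), 0L)
})

test_that("training is seed-deterministic and reports consistent metrics", {
  feats <- tiny_features()
  hp <- hyperparam_set(3, 16, 16, 32, 16)
  f1 <- train_fbccnn(build_model(hp, 8, 110, 12, seed = 4), feats, feats,
                     n_epochs = 3, seed = 4)
  f2 <- train_fbccnn(build_model(hp, 8, 110, 12, seed = 4), feats, feats,
                     n_epochs = 3, seed = 4)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$report$history, f2$report$history)
  expect_equal(nrow(f1$report$history), 3L)
  rep <- f1$report
  expect_true(rep$train_accuracy >= 0 && rep$train_accuracy <= 100)
  expect_equal(sum(rep$confusion), length(feats$labels))
  expect_equal(as.integer(rowSums(rep$confusion)),
               as.integer(table(feats$labels)))
  expect_equal(nrow(tidy(rep)), 12L)
  expect_equal(glance(rep)$test_accuracy, rep$test_accuracy)

  # a class missing from training windows is an error
  sub <- feats
  keep <- feats$labels != 5
  sub$x <- feats$x[, , keep, drop = FALSE]
  sub$labels <- feats$labels[keep]
  expect_error(train_fbccnn(build_model(hp, 8, 110, 12), sub), "class")
})

test_that("test accuracy responds monotonically to SNR", {
  # scaled-down 3-point check: 4 blocks, 15 epochs, one-band model
  accs <- vapply(c(-10, 0, 10), function(snr) {
    ep <- generate_epochs(make_layout("nakanishi12"), 256,
                          synth_config(n_blocks = 4, snr_db = snr, seed = 21,
                                       epoch_s = 2))
    fit <- train_decoder(ep, hyperparam_set(1, 16, 8, 32, 16),
                         n_test_trials = 1, n_epochs = 15, seed = 21)
    fit$report$test_accuracy
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})

test_that("result objects expose plots and tidy summaries", {
  feats <- tiny_features()
  fit <- train_fbccnn(build_model(hyperparam_set(3, 8, 8, 32, 16), 8, 110,
                                  12, seed = 2),
                      feats, feats, n_epochs = 2, seed = 2)
  expect_s3_class(autoplot(fit$report), "ggplot")
  expect_s3_class(plot_training_history(fit), "ggplot")
  expect_s3_class(glance(fit), "tbl_df")
})
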