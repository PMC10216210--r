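#' Slide 1 s windows over epochs
#'
#' Segments every trial into overlapping windows with inherited labels, the
#' data-augmentation step of the training protocol. Window `k` (0-based)
#' starts at sample `round(k * stride_s * fs)` and spans `round(window_s *
#' fs)` samples (half-open interval); windows are generated while they fit,
#' giving `floor((L - W) / (stride_s * fs)) + 1` windows per trial.
#'
#' @param epochs An [ssvep_epochs()] object (typically one band of
#'   [apply_filter_bank()]).
#' @param window_s Window length in seconds.
#' @param stride_s Stride between window starts in seconds.
#' @return An object of class `ssvep_windows`: list with `data` (array
#'   `n_windows x channels x samples`), `labels`, `trial` (source trial id
#'   per window), `block_id`, `fs`, `layout`, and the band index if the
#'   input carried one.
#' @export
segment_epochs <- function(epochs, window_s = 1, stride_s = 0.1) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  d <- dim(epochs$data)
  L <- d[3]
  W <- round(window_s * epochs$fs)
  if (W > L) {
    stop("window is longer than the epoch", call. = FALSE)
  }
  step <- stride_s * epochs$fs
  n_per <- floor((L - W) / step) + 1L
  starts <- round((seq_len(n_per) - 1L) * step)
  n_win <- n_per * d[1]
  data <- array(0, dim = c(n_win, d[2], W))
  i <- 0L
  for (tr in seq_len(d[1])) {
    for (s0 in starts) {
      i <- i + 1L
      data[i, , ] <- epochs$data[tr, , (s0 + 1L):(s0 + W)]
    }
  }
  trial_id <- epochs$trial_id %||% seq_len(d[1])
  structure(
    list(data = data, labels = rep(epochs$labels, each = n_per),
         trial = rep(trial_id, each = n_per),
         block_id = rep(epochs$block_id, each = n_per),
         fs = epochs$fs, layout = epochs$layout, band = epochs$band,
         window_s = window_s, stride_s = stride_s, n_per_trial = n_per),
    class = "ssvep_windows"
  )
}

#' @export
print.ssvep_windows <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ssvep_windows> %d windows (%d/trial) x %d ch x %d samples\n",
              d[1], x$n_per_trial, d[2], d[3]))
  invisible(x)
}

epochs_subset <- function(epochs, idx) {
  out <- ssvep_epochs(epochs$data[idx, , , drop = FALSE], epochs$fs,
                      epochs$labels[idx], epochs$layout, epochs$block_id[idx])
  out$trial_id <- (epochs$trial_id %||% seq_len(dim(epochs$data)[1]))[idx]
  out$band <- epochs$band
  out
}

#' Trial-level train/test split
#'
#' Splits an epoch set at the trial level, stratified per class, before any
#' windowing, so no window of one trial can appear on both sides. For each
#' class, `n_test_trials` trials are drawn at random (seeded) for the test
#' side and the rest go to training.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param n_test_trials Test trials per class; must be fewer than the trials
#'   available per class. `0` puts everything in training.
#' @param seed Integer seed for the draw.
#' @return List with `train` and `test` epoch sets; both carry `trial_id`
#'   giving their source trial indices in `epochs`.
#' @export
split_by_trials <- function(epochs, n_test_trials, seed = 1L) {
  stopifnot(inherits(epochs, "ssvep_epochs"), n_test_trials >= 0)
  test_idx <- integer(0)
  with_seed(seed, {
    for (k in sort(unique(epochs$labels))) {
      k_idx <- which(epochs$labels == k)
      if (n_test_trials >= length(k_idx)) {
        stop("n_test_trials must be fewer than the trials per class",
             call. = FALSE)
      }
      if (n_test_trials > 0) {
        test_idx <- c(test_idx, sample(k_idx, n_test_trials))
      }
    }
  })
  train_idx <- setdiff(seq_along(epochs$labels), test_idx)
  list(train = epochs_subset(epochs, train_idx),
       test = epochs_subset(epochs, sort(test_idx)))
}

#' Filter-bank complex-spectrum features for a set of epochs
#'
#' The standard preprocessing pipeline: the filter bank runs on the full
#' trials (so window edges see no extra filter transient), each sub-band is
#' segmented into windows, and the per-window complex spectra are
#' concatenated across bands.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param fb A [design_filter_bank()] spec (its `n_bands` sets the number of
#'   sub-bands).
#' @param spec A [make_spectrum_spec()] object.
#' @param window_s,stride_s Windowing parameters, see [segment_epochs()].
#' @return An [assemble_features()] object.
#' @export
extract_features <- function(epochs, fb, spec, window_s = 1, stride_s = 0.1) {
  bands <- apply_filter_bank(epochs, fb)
  wins <- lapply(bands, segment_epochs, window_s = window_s,
                 stride_s = stride_s)
  assemble_features(wins, spec)
}

softmax_cols <- function(S) {
  e <- exp(sweep(S, 2, apply(S, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

prelu <- function(A, a) A * ((A > 0) + a * (A <= 0))

bn_backward <- function(dA, Zh, inv, g) {
  M <- ncol(Zh)
  dZh <- dA * g
  list(g = rowSums(dA * Zh), be = rowSums(dA),
       dZ = (inv / M) * (M * dZh - rowSums(dZh) - Zh * rowSums(dZh * Zh)))
}

fbccnn_backward <- function(model, fw, y_onehot) {
  p <- model$params; hp <- model$hp
  B <- fw$B
  probs <- softmax_cols(fw$scores)
  dS <- (probs - y_onehot) / B

  gW3 <- tcrossprod(dS, fw$Fm)
  gb3 <- rowSums(dS)
  dF <- crossprod(p$W3, dS)

  dD2 <- matrix(dF, hp$nk2, model$n_pos * B)
  dP2 <- if (is.null(fw$mask2)) dD2 else dD2 * fw$mask2
  pos2 <- fw$A2 > 0
  dA2 <- dP2 * (pos2 + p$a2 * !pos2)
  ga2 <- sum(dP2 * fw$A2 * !pos2)
  bn2 <- bn_backward(dA2, fw$Z2h, fw$inv2, p$g2)
  dZ2 <- bn2$dZ
  gW2 <- tcrossprod(dZ2, fw$Pat)
  gb2 <- rowSums(dZ2)
  dPat <- crossprod(p$W2, dZ2)

  W <- model$width; Tn <- model$n_pos
  dim(dPat) <- c(hp$nk1, hp$k2, Tn, B)
  dD1 <- matrix(0, hp$nk1, W * B)
  base <- rep((0:(B - 1L)) * W, each = hp$k2) + rep(seq_len(hp$k2), B)
  for (t in seq_len(Tn)) {
    cols_t <- base + (t - 1L) * hp$s2
    sl <- dPat[, , t, ]
    dim(sl) <- c(hp$nk1, hp$k2 * B)
    dD1[, cols_t] <- dD1[, cols_t] + sl
  }
  dP1 <- if (is.null(fw$mask1)) dD1 else dD1 * fw$mask1
  pos1 <- fw$A1 > 0
  dA1 <- dP1 * (pos1 + p$a1 * !pos1)
  ga1 <- sum(dP1 * fw$A1 * !pos1)
  bn1 <- bn_backward(dA1, fw$Z1h, fw$inv1, p$g1)
  dZ1 <- bn1$dZ
  gW1 <- tcrossprod(dZ1, fw$X)
  gb1 <- rowSums(dZ1)

  list(W1 = gW1, b1 = gb1, g1 = bn1$g, be1 = bn1$be, a1 = ga1,
       W2 = gW2, b2 = gb2, g2 = bn2$g, be2 = bn2$be, a2 = ga2,
       W3 = gW3, b3 = gb3)
}

#' Train the complex-spectrum network
#'
#' Mini-batch training with Adam and softmax cross-entropy: by default 50
#' epochs at batch size 32, learning rate 0.001. Batch normalization uses
#' batch statistics during training (running statistics, momentum 0.1, are
#' kept for inference) and dropout masks are drawn per batch. The whole run
#' is a deterministic function of the seed. Accuracy is per window: each
#' window is one classification.
#'
#' @param model An untrained [build_model()] network.
#' @param train_features,test_features [assemble_features()] objects; test
#'   features may be `NULL`.
#' @param n_epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed driving shuffling and dropout.
#' @param verbose Print a line every 10 epochs.
#' @return List of class `fbccnn_fit` with the trained `model` and `report`,
#'   an `ssvep_eval` object carrying the final-epoch training accuracy and
#'   loss, test accuracy, per-class accuracies, the confusion matrix
#'   (rows = true class) and the per-epoch `history` tibble.
#' @export
train_fbccnn <- function(model, train_features, test_features = NULL,
                         n_epochs = 50L, batch_size = 32L, lr = 1e-3,
                         seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "fbccnn"),
            inherits(train_features, "ssvep_features"))
  x <- train_features$x
  y <- train_features$labels
  if (length(unique(y)) < model$n_classes) {
    stop("every class must appear in the training windows", call. = FALSE)
  }
  params_m <- lapply(model$params, function(p) if (is.matrix(p)) p else matrix(p))
  res <- with_seed(seed,
    cpp_fbccnn_train(x, as.integer(y), params_m, model$bn,
                     model_dims(model), model$dropout,
                     as.integer(n_epochs), as.integer(batch_size), lr))
  # weight matrices stay matrices; bias/scale/shift vectors and the PReLU
  # slopes come back as their original vector/scalar shapes
  model$params <- lapply(stats::setNames(nm = names(res$params)), function(nm) {
    p <- res$params[[nm]]
    if (nm %in% c("W1", "W2", "W3")) p else as.numeric(p)
  })
  model$bn <- lapply(res$bn, as.numeric)
  model$trained <- TRUE

  history <- tibble::tibble(epoch = seq_len(n_epochs),
                            loss = res$history[, 1],
                            train_acc = res$history[, 2])
  if (verbose) {
    message(sprintf("final epoch: loss %.4f  train acc %.1f%%",
                    history$loss[n_epochs], history$train_acc[n_epochs]))
  }
  report <- eval_report(model, test_features,
                        train_accuracy = history$train_acc[n_epochs],
                        loss = history$loss[n_epochs], history = history)
  structure(list(model = model, report = report), class = "fbccnn_fit")
}

eval_report <- function(model, test_features, train_accuracy, loss, history) {
  if (!is.null(test_features)) {
    pred <- predict(model, test_features)
    truth <- test_features$labels
    n_cl <- model$n_classes
    confusion <- table(factor(truth, levels = seq_len(n_cl)),
                       factor(pred, levels = seq_len(n_cl)))
    confusion <- matrix(as.integer(confusion), n_cl, n_cl,
                        dimnames = list(true = seq_len(n_cl),
                                        predicted = seq_len(n_cl)))
    per_class <- tibble::tibble(
      class = seq_len(n_cl),
      n = as.integer(rowSums(confusion)),
      accuracy = 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
    )
    test_accuracy <- 100 * mean(pred == truth)
  } else {
    confusion <- NULL; per_class <- NULL; test_accuracy <- NA_real_
  }
  structure(
    list(train_accuracy = train_accuracy, test_accuracy = test_accuracy,
         loss = loss, per_class = per_class, confusion = confusion,
         history = history),
    class = "ssvep_eval"
  )
}

#' @export
print.ssvep_eval <- function(x, ...) {
  cat(sprintf("<ssvep_eval> train %.2f%%  test %s  loss %.4f\n",
              x$train_accuracy,
              if (is.na(x$test_accuracy)) "NA"
              else sprintf("%.2f%%", x$test_accuracy),
              x$loss))
  invisible(x)
}

#' @export
print.fbccnn_fit <- function(x, ...) {
  print(x$model); print(x$report)
  invisible(x)
}

#' @rdname train_fbccnn
#' @param x An `ssvep_eval` report.
#' @export
tidy.ssvep_eval <- function(x, ...) {
  if (is.null(x$per_class)) return(tibble::tibble())
  x$per_class
}

#' @rdname train_fbccnn
#' @export
glance.ssvep_eval <- function(x, ...) {
  tibble::tibble(train_accuracy = x$train_accuracy,
                 test_accuracy = x$test_accuracy, loss = x$loss)
}

#' @export
tidy.fbccnn_fit <- function(x, ...) tidy(x$report)

#' @export
glance.fbccnn_fit <- function(x, ...) glance(x$report)

#' End-to-end decoder run on an epoch set
#'
#' Convenience wrapper for the full protocol: trial-level split, filter-bank
#' decomposition of the full trials, 1 s windowing with 0.1 s stride,
#' complex-spectrum features, then seeded network training and window-level
#' evaluation.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param hp A [hyperparam_set()]; its `nfb` sets the filter-bank depth.
#' @param n_test_trials Held-out trials per class.
#' @param window_s,stride_s Windowing parameters.
#' @param spec A [make_spectrum_spec()]; default derives from `epochs$fs`.
#' @param n_epochs,batch_size,lr Training parameters, see [train_fbccnn()].
#' @param seed Integer seed for split, initialization and training.
#' @param verbose Passed to [train_fbccnn()].
#' @return An `fbccnn_fit` (see [train_fbccnn()]).
#' @export
train_decoder <- function(epochs, hp, n_test_trials = 3L, window_s = 1,
                          stride_s = 0.1, spec = NULL, n_epochs = 50L,
                          batch_size = 32L, lr = 1e-3, seed = 1L,
                          verbose = FALSE) {
  stopifnot(inherits(epochs, "ssvep_epochs"), inherits(hp, "hyperparam_set"))
  if (is.null(spec)) spec <- make_spectrum_spec(epochs$fs)
  fb <- design_filter_bank(hp$nfb, epochs$fs)
  parts <- split_by_trials(epochs, n_test_trials, seed = seed)
  tr_feat <- extract_features(parts$train, fb, spec, window_s, stride_s)
  te_feat <- if (n_test_trials > 0) {
    extract_features(parts$test, fb, spec, window_s, stride_s)
  }
  model <- build_model(hp, n_channels = dim(epochs$data)[2],
                       n_bins = spec$n_bins,
                       n_classes = epochs$layout$n_targets, seed = seed)
  train_fbccnn(model, tr_feat, te_feat, n_epochs = n_epochs,
               batch_size = batch_size, lr = lr, seed = seed,
               verbose = verbose)
}
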