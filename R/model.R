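#' Hyperparameter set for the filter-bank complex-spectrum network
#'
#' The five searchable hyperparameters: number of sub-bands `nfb`, kernel
#' counts `nk1`/`nk2` of the two convolutional layers, and kernel width `k2`
#' and stride `s2` of the second layer. `k2` may not exceed the width of the
#' first layer's output (`2 * n_bins * nfb`) and `s2` may not exceed `k2`;
#' both constraints are checked when a model is built.
#'
#' @param nfb,nk1,nk2,k2,s2 Positive integers.
#' @return A list of class `hyperparam_set`.
#' @examples
#' hyperparam_set(3, 64, 64, 64, 64)
#' @export
hyperparam_set <- function(nfb, nk1, nk2, k2, s2) {
  v <- c(nfb = nfb, nk1 = nk1, nk2 = nk2, k2 = k2, s2 = s2)
  if (any(v < 1) || any(v != round(v))) {
    stop("all hyperparameters must be positive integers", call. = FALSE)
  }
  if (s2 > k2) stop("stride s2 may not exceed kernel width k2", call. = FALSE)
  v <- stats::setNames(as.integer(v), names(v))
  structure(as.list(v), class = "hyperparam_set")
}

#' @export
print.hyperparam_set <- function(x, ...) {
  cat(sprintf("<hyperparam_set> nfb=%d nk1=%d nk2=%d k2=%d s2=%d\n",
              x$nfb, x$nk1, x$nk2, x$k2, x$s2))
  invisible(x)
}

#' Width of the flattened layer feeding the dense output
#'
#' The second convolutional layer slides a `1 x k2` kernel with stride `s2`
#' over the `2 * n_bins * nfb`-wide feature maps, so the dense layer sees
#' \deqn{N_f = \left(\left\lfloor \frac{2\,\mathrm{NFFT}\,N_{fb} - K_2}{S_2}
#' \right\rfloor + 1\right) \times N_{k2}}
#' values.
#'
#' @param hp A [hyperparam_set()].
#' @param n_bins Retained FFT bins per channel per band (NFFT).
#' @return Integer flattened width.
#' @examples
#' flatten_width(hyperparam_set(3, 64, 64, 64, 64), n_bins = 110)
#' @export
flatten_width <- function(hp, n_bins) {
  stopifnot(inherits(hp, "hyperparam_set"), n_bins >= 1)
  width <- 2L * as.integer(n_bins) * hp$nfb
  if (hp$k2 > width) {
    stop("kernel width k2 exceeds the feature width 2 * n_bins * nfb",
         call. = FALSE)
  }
  (as.integer((width - hp$k2) %/% hp$s2) + 1L) * hp$nk2
}

#' Channel-number-based hyperparameter sets
#'
#' Derives hyperparameters from the channel count `nch`, the convention of
#' earlier complex-spectrum CNNs: the one-band variant uses
#' `(nfb=1, nk1=8*nch, nk2=2*nch, k2=8*nch, s2=nch)` and the three-band
#' variant sets all four to `8*nch` with `nfb=3`. Values are clamped to the
#' `k2 <= 2*n_bins*nfb` and `s2 <= k2` constraints afterwards; any clamping
#' is reported via a `clamped` attribute (and a warning).
#'
#' @param nch Channel count.
#' @param variant `"one_band"` or `"three_band"`.
#' @param n_bins Retained FFT bins, used for the `k2` clamp (default 110).
#' @return A [hyperparam_set()]; attribute `clamped` is `TRUE` if any value
#'   was reduced.
#' @examples
#' channel_based_hyperparams(8, "three_band")
#' @export
channel_based_hyperparams <- function(nch, variant = c("one_band", "three_band"),
                                      n_bins = 110L) {
  variant <- match.arg(variant)
  nch <- as.integer(nch)
  stopifnot(nch >= 1L)
  raw <- switch(variant,
    one_band = c(nfb = 1L, nk1 = 8L * nch, nk2 = 2L * nch, k2 = 8L * nch,
                 s2 = nch),
    three_band = c(nfb = 3L, nk1 = 8L * nch, nk2 = 8L * nch, k2 = 8L * nch,
                   s2 = 8L * nch)
  )
  k2 <- min(raw[["k2"]], 2L * as.integer(n_bins) * raw[["nfb"]])
  s2 <- min(raw[["s2"]], k2)
  clamped <- k2 < raw[["k2"]] || s2 < raw[["s2"]]
  if (clamped) {
    warning(sprintf("hyperparameters clamped to k2=%d, s2=%d for n_bins=%d",
                    k2, s2, n_bins), call. = FALSE)
  }
  hp <- hyperparam_set(raw[["nfb"]], raw[["nk1"]], raw[["nk2"]], k2, s2)
  attr(hp, "clamped") <- clamped
  hp
}

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build the two-convolution-layer complex-spectrum classifier
#'
#' Constructs the network of the filter-bank complex-spectrum decoder:
#' layer 1 applies `nk1` kernels of shape `channels x 1` (stride 1) that mix
#' all channels at each frequency column; layer 2 applies `nk2` kernels of
#' shape `1 x k2` with stride `s2` across the width; each convolution is
#' followed by batch normalization, a PReLU activation (one learnable slope
#' per layer, initialized at 0.25) and dropout at rate 0.5; a final dense
#' layer maps the flattened features to `n_classes` scores. Convolution
#' weights use seeded He-uniform initialization.
#'
#' @param hp A [hyperparam_set()].
#' @param n_channels EEG channel count.
#' @param n_bins Retained FFT bins per channel per band.
#' @param n_classes Number of stimulus targets.
#' @param dropout Dropout rate (training only).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fbccnn`; its `$n_flat` equals
#'   [flatten_width()] of `hp`.
#' @examples
#' m <- build_model(hyperparam_set(3, 64, 64, 64, 64), 8, 110, 12, seed = 1)
#' m$n_flat
#' @export
build_model <- function(hp, n_channels, n_bins, n_classes, dropout = 0.5,
                        seed = 1L) {
  stopifnot(inherits(hp, "hyperparam_set"))
  width <- 2L * as.integer(n_bins) * hp$nfb
  n_flat <- flatten_width(hp, n_bins)       # validates k2 <= width
  n_pos <- n_flat %/% hp$nk2
  params <- with_seed(seed, list(
    W1 = he_uniform(hp$nk1, n_channels, n_channels),
    b1 = numeric(hp$nk1),
    g1 = rep(1, hp$nk1), be1 = numeric(hp$nk1), a1 = 0.25,
    W2 = he_uniform(hp$nk2, hp$nk1 * hp$k2, hp$nk1 * hp$k2),
    b2 = numeric(hp$nk2),
    g2 = rep(1, hp$nk2), be2 = numeric(hp$nk2), a2 = 0.25,
    W3 = he_uniform(n_classes, n_flat, n_flat),
    b3 = numeric(n_classes)
  ))
  structure(
    list(hp = hp, n_channels = as.integer(n_channels),
         n_bins = as.integer(n_bins), n_classes = as.integer(n_classes),
         dropout = dropout, width = width, n_pos = n_pos, n_flat = n_flat,
         params = params,
         bn = list(m1 = numeric(hp$nk1), v1 = rep(1, hp$nk1),
                   m2 = numeric(hp$nk2), v2 = rep(1, hp$nk2)),
         seed = as.integer(seed), trained = FALSE),
    class = "fbccnn"
  )
}

#' @export
print.fbccnn <- function(x, ...) {
  n_par <- sum(lengths(lapply(x$params, as.numeric)))
  cat(sprintf(
    "<fbccnn> %d ch x %d wide -> conv(%d) -> conv(%d, k=%d, s=%d) -> %d -> %d classes (%s, %d params)\n",
    x$n_channels, x$width, x$hp$nk1, x$hp$nk2, x$hp$k2, x$hp$s2, x$n_flat,
    x$n_classes, if (x$trained) "trained" else "untrained", n_par))
  invisible(x)
}

bn_eps <- 1e-5

# im2col column index for the second convolution: T output positions per
# sample, samples laid out side by side (width W each) in a wide matrix.
conv2_cols <- function(width, k2, s2, n_pos, n_batch) {
  starts <- as.vector(outer((0:(n_pos - 1L)) * s2, (0:(n_batch - 1L)) * width, "+"))
  rep(starts, each = k2) + rep(seq_len(k2), times = n_pos * n_batch)
}

model_dims <- function(model) {
  c(nch = model$n_channels, width = model$width, k2 = model$hp$k2,
    s2 = model$hp$s2, n_pos = model$n_pos, n_classes = model$n_classes)
}

# Compiled batch step: forward pass, and when `y` is supplied also the
# softmax cross-entropy loss, hit count and parameter gradients. Dropout
# masks are drawn from R's RNG stream, so runs are seed-deterministic.
fbccnn_batch <- function(model, x, training = FALSE, y = integer(0)) {
  X <- matrix(x, model$n_channels)
  cpp_fbccnn_batch(X, model$params, model$bn, model_dims(model),
                   model$dropout, training, as.integer(y))
}

# Pure-R reference forward pass, kept as an independent check of the
# compiled path. x: array channels x width x B (or matching matrix
# channels x (width*B)). Returns scores and, if keep = TRUE, the
# intermediates needed for backprop. In training mode batch statistics are
# used for normalization and dropout masks are drawn from the current RNG
# stream; in eval mode running statistics are used and dropout is off.
fbccnn_forward <- function(model, x, training = FALSE, keep = FALSE) {
  p <- model$params; hp <- model$hp
  W <- model$width; Tn <- model$n_pos
  B <- length(x) / (model$n_channels * W)
  stopifnot(B == round(B))
  B <- as.integer(B)
  X <- matrix(x, model$n_channels, W * B)

  Z1 <- p$W1 %*% X + p$b1
  if (training) {
    m1 <- rowMeans(Z1); v1 <- rowMeans(Z1^2) - m1^2
  } else {
    m1 <- model$bn$m1; v1 <- model$bn$v1
  }
  inv1 <- 1 / sqrt(v1 + bn_eps)
  Z1h <- (Z1 - m1) * inv1
  A1 <- p$g1 * Z1h + p$be1
  P1 <- A1 * ((A1 > 0) + p$a1 * (A1 <= 0))
  if (training && model$dropout > 0) {
    mask1 <- (runif(length(P1)) >= model$dropout) / (1 - model$dropout)
    D1 <- P1 * mask1
  } else {
    mask1 <- NULL
    D1 <- P1
  }

  cols <- conv2_cols(W, hp$k2, hp$s2, Tn, B)
  Pat <- D1[, cols, drop = FALSE]
  dim(Pat) <- c(hp$nk1 * hp$k2, Tn * B)
  Z2 <- p$W2 %*% Pat + p$b2
  if (training) {
    m2 <- rowMeans(Z2); v2 <- rowMeans(Z2^2) - m2^2
  } else {
    m2 <- model$bn$m2; v2 <- model$bn$v2
  }
  inv2 <- 1 / sqrt(v2 + bn_eps)
  Z2h <- (Z2 - m2) * inv2
  A2 <- p$g2 * Z2h + p$be2
  P2 <- A2 * ((A2 > 0) + p$a2 * (A2 <= 0))
  if (training && model$dropout > 0) {
    mask2 <- (runif(length(P2)) >= model$dropout) / (1 - model$dropout)
    D2 <- P2 * mask2
  } else {
    mask2 <- NULL
    D2 <- P2
  }

  Fm <- matrix(D2, model$n_flat, B)
  S <- p$W3 %*% Fm + p$b3
  out <- list(scores = S, B = B)
  if (training) out$batch_stats <- list(m1 = m1, v1 = v1, m2 = m2, v2 = v2)
  if (keep) {
    out <- c(out, list(X = X, Z1h = Z1h, inv1 = inv1, A1 = A1, mask1 = mask1,
                       D1 = D1, cols = cols, Pat = Pat, Z2h = Z2h,
                       inv2 = inv2, A2 = A2, mask2 = mask2, Fm = Fm))
  }
  out
}

#' Predict class scores or labels
#'
#' Runs the network in inference mode (running batch-norm statistics,
#' dropout off) over feature windows, in chunks to bound memory.
#'
#' @param object A trained or untrained `fbccnn` model.
#' @param features An [assemble_features()] object or a bare
#'   `channels x width x n` array.
#' @param type `"class"` for 1-based class indices, `"score"` for the raw
#'   `n x n_classes` score matrix, `"prob"` for softmax probabilities.
#' @param chunk Windows per forward chunk.
#' @param ... Unused.
#' @return Integer vector, or numeric matrix for `"score"`/`"prob"`.
#' @export
predict.fbccnn <- function(object, features, type = c("class", "score", "prob"),
                           chunk = 256L, ...) {
  type <- match.arg(type)
  x <- if (inherits(features, "ssvep_features")) features$x else features
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == object$n_channels,
            dim(x)[2] == object$width)
  n <- dim(x)[3]
  scores <- matrix(0, n, object$n_classes)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    fw <- fbccnn_batch(object, x[, , i0:i1, drop = FALSE], training = FALSE)
    scores[i0:i1, ] <- t(fw$scores)
  }
  switch(type,
    class = max.col(scores, ties.method = "first"),
    score = scores,
    prob = {
      e <- exp(scores - apply(scores, 1, max))
      e / rowSums(e)
    }
  )
}
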