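#' Descriptors for the two public SSVEP datasets
#'
#' Returns the recording parameters of the named public dataset: the
#' 12-target, 8-channel set sampled at 256 Hz (15 blocks of 4 s trials,
#' 0.135 s visual latency) or the 40-target, 64-channel benchmark set
#' sampled at 250 Hz (6 blocks of 5 s trials, 0.5 s cue plus 0.14 s
#' latency).
#'
#' @param name `"nakanishi"` or `"benchmark"`.
#' @return List of class `dataset_descriptor` with fields `name`, `fs`,
#'   `n_channels`, `n_targets`, `n_blocks`, `epoch_s`, `latency_s`,
#'   `layout`.
#' @export
dataset_descriptor <- function(name = c("nakanishi", "benchmark")) {
  name <- match.arg(name)
  switch(name,
    nakanishi = structure(
      list(name = "nakanishi", fs = 256, n_channels = 8L, n_targets = 12L,
           n_blocks = 15L, epoch_s = 4, latency_s = 0.135,
           layout = make_layout("nakanishi12")),
      class = "dataset_descriptor"),
    benchmark = structure(
      list(name = "benchmark", fs = 250, n_channels = 64L, n_targets = 40L,
           n_blocks = 6L, epoch_s = 5, latency_s = 0.5 + 0.14,
           layout = make_layout("benchmark40")),
      class = "dataset_descriptor")
  )
}

#' Drop the visual-latency lead-in of every trial
#'
#' Removes the first `latency_s` seconds of each epoch, the standard
#' stimulus-onset correction before decoding.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param latency_s Seconds to drop from the start of every trial.
#' @return The trimmed epoch set.
#' @export
drop_latency <- function(epochs, latency_s) {
  stopifnot(inherits(epochs, "ssvep_epochs"), latency_s >= 0)
  n_drop <- round(latency_s * epochs$fs)
  if (n_drop == 0L) return(epochs)
  d <- dim(epochs$data)
  if (n_drop >= d[3]) stop("latency longer than the epoch", call. = FALSE)
  out <- ssvep_epochs(epochs$data[, , (n_drop + 1L):d[3], drop = FALSE],
                      epochs$fs, epochs$labels, epochs$layout,
                      epochs$block_id)
  out$trial_id <- epochs$trial_id
  out
}

#' Read a public SSVEP recording from a .mat file
#'
#' Maps one subject's recording to an [ssvep_epochs()] object with trials
#' ordered block-major / target-minor and the latency lead-in trimmed per
#' the descriptor. Requires the `R.matlab` package. Assumed array layouts:
#' the 12-target release stores `eeg` as `targets x channels x samples x
#' blocks`; the 40-target benchmark stores `data` as `channels x samples x
#' targets x blocks`. Shape mismatches fail with the offending dimension
#' named.
#'
#' @param path Path to the subject's `.mat` file.
#' @param descriptor A [dataset_descriptor()].
#' @return An [ssvep_epochs()] object.
#' @export
read_ssvep_mat <- function(path, descriptor) {
  stopifnot(inherits(descriptor, "dataset_descriptor"))
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (!requireNamespace("R.matlab", quietly = TRUE)) {
    stop("reading .mat recordings requires the R.matlab package",
         call. = FALSE)
  }
  raw <- R.matlab::readMat(path)
  key <- if (descriptor$name == "nakanishi") "eeg" else "data"
  if (is.null(raw[[key]])) {
    stop(sprintf("variable '%s' missing from %s", key, path), call. = FALSE)
  }
  arr <- raw[[key]]
  dims <- dim(arr)
  expect <- if (descriptor$name == "nakanishi") {
    c(descriptor$n_targets, descriptor$n_channels, NA, descriptor$n_blocks)
  } else {
    c(descriptor$n_channels, NA, descriptor$n_targets, descriptor$n_blocks)
  }
  for (i in seq_along(expect)) {
    if (!is.na(expect[i]) && dims[i] != expect[i]) {
      stop(sprintf("dimension %d of '%s' is %d, expected %d",
                   i, key, dims[i], expect[i]), call. = FALSE)
    }
  }
  n_samp <- if (descriptor$name == "nakanishi") dims[3] else dims[2]
  n_trials <- descriptor$n_blocks * descriptor$n_targets
  data <- array(0, dim = c(n_trials, descriptor$n_channels, n_samp))
  labels <- integer(n_trials); blocks <- integer(n_trials)
  i <- 0L
  for (b in seq_len(descriptor$n_blocks)) {
    for (k in seq_len(descriptor$n_targets)) {
      i <- i + 1L
      data[i, , ] <- if (descriptor$name == "nakanishi") {
        arr[k, , , b]
      } else {
        arr[, , k, b]
      }
      labels[i] <- k; blocks[i] <- b
    }
  }
  ep <- ssvep_epochs(data, descriptor$fs, labels, descriptor$layout, blocks)
  drop_latency(ep, descriptor$latency_s)
}

#' Write / read an epoch-set archive
#'
#' Serializes an [ssvep_epochs()] object to a single-file archive holding
#' the plain fields `data`, `fs`, `labels`, `block_id`, `trial_id` and the
#' layout parameters; reading reconstructs a bit-identical epoch set.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param path Archive path.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns the epoch set.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  lay <- epochs$layout
  payload <- list(
    data = epochs$data, fs = epochs$fs, labels = epochs$labels,
    block_id = epochs$block_id,
    trial_id = epochs$trial_id %||% seq_len(dim(epochs$data)[1]),
    layout = list(name = lay$name, n_targets = lay$n_targets, f0 = lay$f0,
                  delta_f = lay$delta_f, phi0 = lay$phi0,
                  delta_phi = lay$delta_phi)
  )
  saveRDS(payload, path, version = 2)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  p <- readRDS(path)
  lay <- make_layout(n_targets = p$layout$n_targets, f0 = p$layout$f0,
                     delta_f = p$layout$delta_f, phi0 = p$layout$phi0,
                     delta_phi = p$layout$delta_phi)
  lay$name <- p$layout$name
  ep <- ssvep_epochs(p$data, p$fs, p$labels, lay, p$block_id)
  ep$trial_id <- p$trial_id
  ep
}
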