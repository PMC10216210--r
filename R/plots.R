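#' Plot a confusion matrix heatmap
#'
#' @param x An `ssvep_eval` report from [train_fbccnn()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssvep_eval <- function(x, ...) {
  if (is.null(x$confusion)) {
    stop("report carries no test-set confusion matrix", call. = FALSE)
  }
  df <- as.data.frame(as.table(x$confusion))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted target", y = "true target",
                  title = sprintf("window-level test accuracy %.1f%%",
                                  x$test_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Loss and training accuracy per epoch for a fitted decoder.
#'
#' @param fit An `fbccnn_fit` from [train_fbccnn()] or [train_decoder()].
#' @return A ggplot object.
#' @export
plot_training_history <- function(fit) {
  h <- if (inherits(fit, "fbccnn_fit")) fit$report$history else fit$history
  long <- tidyr::pivot_longer(h, c("loss", "train_acc"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot hyperparameter/performance correlations
#'
#' @param x An `agd_correlations` object from [hyperparam_correlations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agd_correlations <- function(x, ...) {
  ggplot2::ggplot(x$correlations,
                  ggplot2::aes(x = .data$param, y = .data$r,
                               fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "hyperparameter", y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
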