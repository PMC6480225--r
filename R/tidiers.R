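#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom tibble as_tibble
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

#' Tidy a confusion matrix into long form
#'
#' @param x A `har_confusion` object.
#' @param ... Unused.
#' @return Tibble with `truth`, `prediction`, `n`, `percent` (row-
#'   normalized, `NA` for unsupported rows).
#' @method tidy har_confusion
#' @export
tidy.har_confusion <- function(x, ...) {
  k <- length(x$class_names)
  tibble::tibble(
    truth = rep(x$class_names, times = k),
    prediction = rep(x$class_names, each = k),
    n = as.integer(x$counts[cbind(rep(seq_len(k), k), rep(seq_len(k), each = k))]),
    percent = x$row_percent[cbind(rep(seq_len(k), k), rep(seq_len(k), each = k))]
  )
}

#' One-row summary of a confusion matrix
#' @param x A `har_confusion` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_correct`, `accuracy` (overall percent) and
#'   `mean_average` (unweighted mean per-class recall, percent).
#' @method glance har_confusion
#' @export
glance.har_confusion <- function(x, ...) {
  n <- sum(x$counts)
  correct <- sum(diag(x$counts))
  tibble::tibble(n = n, n_correct = correct,
                 accuracy = 100 * correct / n,
                 mean_average = x$mean_average)
}

#' Heatmap of the row-normalized confusion matrix
#' @param object A `har_confusion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot har_confusion
#' @export
autoplot.har_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::scale_y_discrete(limits = rev(object$class_names)) +
    ggplot2::scale_x_discrete(limits = object$class_names) +
    ggplot2::labs(x = "predicted", y = "true",
                  fill = "% of row",
                  title = sprintf("mean average accuracy %.1f%%",
                                  object$mean_average)) +
    ggplot2::theme_minimal()
}

#' Per-epoch training history of a fit
#' @param x A `coarsefine_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, step, train/validation loss and
#'   accuracy).
#' @method tidy coarsefine_fit
#' @export
tidy.coarsefine_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x A `coarsefine_fit`.
#' @param ... Unused.
#' @method glance coarsefine_fit
#' @export
glance.coarsefine_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), steps = last$step,
                 train_loss = last$train_loss, train_acc = last$train_acc,
                 val_loss = last$val_loss, val_acc = last$val_acc)
}

#' Learning curves of a fit
#' @param object A `coarsefine_fit`.
#' @param metric `"loss"` or `"accuracy"`.
#' @param ... Unused.
#' @return A ggplot object with train (and, if recorded, validation)
#'   curves over epochs.
#' @method autoplot coarsefine_fit
#' @export
autoplot.coarsefine_fit <- function(object, metric = c("loss", "accuracy"),
                                    ...) {
  metric <- match.arg(metric)
  h <- object$history
  cols <- if (metric == "loss") c(train = "train_loss", validation = "val_loss")
          else c(train = "train_acc", validation = "val_acc")
  df <- dplyr::bind_rows(lapply(names(cols), function(set) {
    tibble::tibble(epoch = h$epoch, set = set, value = h[[cols[[set]]]])
  }))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = metric, title = paste("training", metric)) +
    ggplot2::theme_minimal()
}

#' Kernel-size sweep curve
#' @param object A `har_sweep` tibble from [kernel_size_sweep()].
#' @param ... Unused.
#' @return A ggplot object of accuracy versus kernel length.
#' @method autoplot har_sweep
#' @export
autoplot.har_sweep <- function(object, ...) {
  df <- object[object$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kernel_length,
                                   y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "convolution kernel length", y = "accuracy (%)",
                  title = "kernel-size sensitivity") +
    ggplot2::theme_minimal()
}
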