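#' Build a confusion matrix from true and predicted class indices
#'
#' Rows are true classes, columns predictions. The row-normalized
#' percentage view divides each row by its support (rows with zero support
#' are flagged and left `NA` rather than divided); the mean average
#' accuracy is the unweighted mean of the per-class recalls (the diagonal
#' of the percentage view) over supported rows.
#'
#' @param truth,predicted Integer vectors of 0-based class indices.
#' @param class_names Ordered class names.
#' @return An object of class `har_confusion` with elements `counts`,
#'   `row_percent`, `mean_average`, `class_names`, `unsupported`.
#' @export
confusion_matrix <- function(truth, predicted, class_names) {
  k <- length(class_names)
  stopifnot(length(truth) == length(predicted))
  counts <- matrix(0L, k, k, dimnames = list(true = class_names,
                                             predicted = class_names))
  for (i in seq_along(truth)) {
    counts[truth[i] + 1L, predicted[i] + 1L] <-
      counts[truth[i] + 1L, predicted[i] + 1L] + 1L
  }
  support <- rowSums(counts)
  row_percent <- counts * NA_real_
  supported <- support > 0
  row_percent[supported, ] <- 100 * counts[supported, , drop = FALSE] /
    support[supported]
  mean_average <- mean(diag(row_percent)[supported])
  structure(list(counts = counts, row_percent = row_percent,
                 mean_average = mean_average, class_names = class_names,
                 unsupported = class_names[!supported]),
            class = "har_confusion")
}

#' Evaluate a model on a dataset
#'
#' Predicts every window with the fused head, tallies the 6 x 6 confusion
#' matrix and computes per-class recalls and their unweighted mean (the
#' mean average accuracy).
#'
#' @param model A `coarsefine_model`.
#' @param dataset A non-empty [har_dataset] whose vocabulary size matches
#'   the model's class count.
#' @return A `har_confusion` object; the mean average accuracy is its
#'   `mean_average` element, in percent.
#' @export
evaluate <- function(model, dataset) {
  stopifnot(inherits(model, "coarsefine_model"),
            inherits(dataset, "har_dataset"))
  if (n_windows(dataset) == 0) stop("cannot evaluate an empty dataset",
                                    call. = FALSE)
  vocab <- vocab_names(dataset$vocabulary)
  if (length(vocab) != model$cfg$n_classes) {
    stop("dataset vocabulary size (", length(vocab),
         ") does not match the model's class count (",
         model$cfg$n_classes, ")", call. = FALSE)
  }
  pred <- predict_classes(model, dataset)
  confusion_matrix(dataset$labels, pred, vocab)
}

#' @export
print.har_confusion <- function(x, digits = 1, ...) {
  cat("<har_confusion> row-normalized percentages (rows = true class)\n")
  print(round(x$row_percent, digits))
  cat(sprintf("mean average accuracy: %.2f%%\n", x$mean_average))
  if (length(x$unsupported)) {
    cat("classes without test windows:",
        paste(x$unsupported, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a dataset under an evaluation protocol
#'
#' `subject_independent` puts whole subjects on one side or the other, so
#' train and test subject sets are disjoint — the generalization protocol.
#' `subject_dependent` splits at the window level irrespective of subject.
#'
#' @param dataset A [har_dataset] with subject ids.
#' @param mode `"subject_independent"` or `"subject_dependent"`.
#' @param fraction Fraction assigned to the training side (of subjects or
#'   of windows, depending on mode). Default 0.7.
#' @param seed Seed for the random assignment.
#' @return List with [har_dataset] elements `train` and `test`.
#' @export
protocol_split <- function(dataset,
                           mode = c("subject_independent", "subject_dependent"),
                           fraction = 0.7, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "har_dataset"), fraction > 0, fraction < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_windows(dataset)
  if (mode == "subject_independent") {
    subjects <- unique(dataset$subjects)
    if (length(subjects) < 2) {
      stop("subject-independent split needs at least 2 subjects",
           call. = FALSE)
    }
    n_train <- max(1L, min(length(subjects) - 1L,
                           round(fraction * length(subjects))))
    train_subjects <- sample(subjects, n_train)
    in_train <- dataset$subjects %in% train_subjects
  } else {
    n_train <- round(fraction * n)
    in_train <- logical(n)
    in_train[sample.int(n, n_train)] <- TRUE
  }
  train <- dataset[in_train]
  test <- dataset[!in_train]
  train$split_tag <- "train"
  test$split_tag <- "test"
  list(train = train, test = test)
}

#' Kernel-size sensitivity sweep
#'
#' Retrains the default architecture once per candidate convolution kernel
#' length (fresh seed-derived initialization each time) and records the
#' held-out mean accuracy, reproducing the filter-size sensitivity
#' analysis. Kernel lengths whose shape chain is invalid for the input
#' length are skipped with a warning and recorded as missing.
#'
#' @param kernel_lengths Integer vector of kernel lengths to try.
#' @param train_set,test_set [har_dataset] objects.
#' @param train_cfg A [training_config()].
#' @param base_cfg Optional function `(kernel_length) -> coarsefine_config`;
#'   defaults to [default_config()] with the sweep's input geometry.
#' @return A tibble of class `har_sweep` with columns `kernel_length`,
#'   `accuracy` (percent, `NA` when skipped) and `status`.
#' @export
kernel_size_sweep <- function(kernel_lengths, train_set, test_set,
                              train_cfg = quick_training_config(),
                              base_cfg = NULL) {
  stopifnot(length(kernel_lengths) >= 1)
  d <- dim(train_set$samples)
  if (is.null(base_cfg)) {
    base_cfg <- function(k) default_config(input_length = d[2],
                                           input_channels = d[3],
                                           kernel_length = k)
  }
  rows <- purrr::map(kernel_lengths, function(k) {
    cfg <- tryCatch(base_cfg(k), error = identity)
    ok <- !inherits(cfg, "error")
    if (ok) {
      ok <- tryCatch({fused_feature_length(cfg); TRUE},
                     error = function(e) FALSE)
    }
    if (!ok) {
      warning("kernel length ", k, " yields an invalid shape chain; skipped",
              call. = FALSE)
      return(tibble::tibble(kernel_length = k, accuracy = NA_real_,
                            status = "skipped"))
    }
    model <- build_model(cfg, seed = train_cfg$seed + k)
    fit <- train(model, train_set, train_cfg)
    acc <- 100 * mean(predict_classes(fit$model, test_set) == test_set$labels)
    tibble::tibble(kernel_length = k, accuracy = acc, status = "ok")
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("har_sweep", class(out))
  out
}
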