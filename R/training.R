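#' Training hyperparameter configuration
#'
#' Defaults follow the reference experimental setup for the full-scale
#' benchmark runs: learning rate 1e-4, weight decay 5e-5, momentum ramped
#' from 0.5 to 0.99 over training, minibatches of 500 and up to 2000
#' epochs. [quick_training_config()] is the desk-scale profile used for the
#' synthetic experiments and tests.
#'
#' @param learning_rate SGD step size.
#' @param weight_decay L2 penalty coefficient, applied to weights (not
#'   biases) inside the optimizer step.
#' @param momentum_start,momentum_end Momentum at the first and last epoch;
#'   linearly interpolated in between (see [momentum_at()]).
#' @param batch_size Minibatch size; the last incomplete minibatch of an
#'   epoch is used, not dropped.
#' @param max_epochs Number of epochs to run.
#' @param seed Master seed: weight initialization noise is the model's own
#'   seed, but epoch shuffles and dropout masks derive from this.
#' @param validation_fraction Fraction of the training set held out for
#'   per-epoch validation when no explicit validation set is supplied.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, weight_decay = 5e-5,
                            momentum_start = 0.5, momentum_end = 0.99,
                            batch_size = 500, max_epochs = 2000,
                            seed = 1L, validation_fraction = 0) {
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (momentum_start < 0 || momentum_start > momentum_end ||
      momentum_end >= 1) {
    stop("need 0 <= momentum_start <= momentum_end < 1", call. = FALSE)
  }
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum_start = momentum_start,
                 momentum_end = momentum_end,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "training_config")
}

#' @rdname training_config
#' @param ... Overrides passed on to [training_config()].
#' @export
quick_training_config <- function(...) {
  defaults <- list(learning_rate = 0.01, weight_decay = 5e-5,
                   batch_size = 64, max_epochs = 60, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(training_config, args)
}

#' Momentum at a given epoch
#'
#' Linear ramp from `momentum_start` at epoch 0 to `momentum_end` at the
#' final epoch (`max_epochs - 1`).
#'
#' @param epoch 0-based epoch index.
#' @param cfg A [training_config()].
#' @return Momentum coefficient.
#' @examples
#' momentum_at(0, training_config())     # 0.5
#' momentum_at(1999, training_config())  # 0.99
#' @export
momentum_at <- function(epoch, cfg) {
  stopifnot(epoch >= 0, epoch < cfg$max_epochs)
  if (cfg$max_epochs == 1L) return(cfg$momentum_end)
  cfg$momentum_start + (cfg$momentum_end - cfg$momentum_start) *
    epoch / (cfg$max_epochs - 1)
}

#' Multi-head cross-entropy loss
#'
#' The total training loss sums one cross-entropy term per head — the three
#' per-branch auxiliary soft-max heads plus the fused classifier — averaged
#' over the batch: `mean_b sum_h w_h * (-log p_h(true class))`. With
#' weights `(0, 0, 0, 1)` it reduces to the standard cross-entropy of the
#' fused head. Probabilities are clamped at 1e-12 before the log, with a
#' warning, so a confidently wrong head yields a large finite loss.
#' The L2 weight-decay penalty is applied inside the optimizer step, not
#' here.
#'
#' @param head_probs List of 4 probability matrices `[batch, n_classes]`
#'   in head order fine, medium, coarse, fused.
#' @param labels Integer vector of 0-based true class indices.
#' @param weights Numeric length-4 head weights (default all 1).
#' @return Non-negative scalar loss.
#' @examples
#' perfect <- matrix(c(1, 0, 0, 0, 0, 0), 1, 6)
#' total_loss(rep(list(perfect), 4), labels = 0L)  # 0
#' @export
total_loss <- function(head_probs, labels, weights = rep(1, length(head_probs))) {
  stopifnot(length(head_probs) >= 1,
            length(weights) == length(head_probs))
  B <- nrow(head_probs[[1]])
  stopifnot(length(labels) == B)
  idx <- cbind(seq_len(B), as.integer(labels) + 1L)
  loss <- 0
  for (h in seq_along(head_probs)) {
    p <- head_probs[[h]][idx]
    if (any(p < 1e-12)) {
      warning("probability at the true class clamped at 1e-12", call. = FALSE)
      p <- pmax(p, 1e-12)
    }
    loss <- loss + weights[h] * mean(-log(p))
  }
  loss
}

# elementwise update over the nested params/velocity/grads structure
sgd_update <- function(params, velocity, grads, lr, momentum, weight_decay) {
  step <- function(p, v, g, is_weight) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in names(p)) {
        r <- step(p[[nm]], v[[nm]], g[[nm]], is_weight = identical(nm, "W"))
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      if (is.null(names(p))) {
        for (i in seq_along(p)) {
          r <- step(p[[i]], v[[i]], g[[i]], is_weight = FALSE)
          out_p[[i]] <- r$p; out_v[[i]] <- r$v
        }
      }
      list(p = out_p, v = out_v)
    } else {
      if (is_weight && weight_decay > 0) g <- g + weight_decay * p
      v <- momentum * v - lr * g
      list(p = p + v, v = v)
    }
  }
  step(params, velocity, grads, FALSE)
}

zero_like <- function(params) {
  if (is.list(params)) lapply(params, zero_like) else params * 0
}

#' Train a coarse-fine model with momentum SGD
#'
#' Seeded-shuffled minibatch stochastic gradient descent on the multi-head
#' cross-entropy loss, with a per-epoch linear momentum ramp and L2 weight
#' decay on weights (biases excluded). Dropout with the configured
#' keep-probability is applied to the fused feature vector during training
#' only. Runs are deterministic for a given seed in single-threaded
#' execution: the shuffle and dropout RNG is reseeded each epoch from the
#' master seed.
#'
#' @param model A [build_model()] result.
#' @param train_set A [har_dataset].
#' @param cfg A [training_config()].
#' @param val_set Optional [har_dataset] evaluated after every epoch; when
#'   omitted and `validation_fraction > 0`, a seeded window-level split of
#'   `train_set` is used.
#' @param verbose Print a progress line every `verbose` epochs (0 = quiet).
#' @return A list of class `coarsefine_fit`: `model` (trained), `history`
#'   (tibble with epoch, step, train_loss, train_acc, val_loss, val_acc),
#'   `train_cfg`.
#' @export
train <- function(model, train_set, cfg = training_config(), val_set = NULL,
                  verbose = 0) {
  stopifnot(inherits(model, "coarsefine_model"),
            inherits(train_set, "har_dataset"))
  if (n_windows(train_set) == 0) stop("empty training set", call. = FALSE)
  n_class <- model$cfg$n_classes
  if (max(train_set$labels) >= n_class) {
    stop("training labels exceed the model's class count", call. = FALSE)
  }
  if (is.null(val_set) && cfg$validation_fraction > 0) {
    sp <- protocol_split(train_set, "subject_dependent",
                         fraction = 1 - cfg$validation_fraction,
                         seed = cfg$seed)
    train_set <- sp$train
    val_set <- sp$test
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  params <- model$params
  velocity <- zero_like(params)
  n <- n_windows(train_set)
  head_w <- c(model$cfg$aux_head_weights, 1)
  hist <- vector("list", cfg$max_epochs)
  step_count <- 0L

  for (epoch in seq_len(cfg$max_epochs) - 1L) {
    set.seed(as.integer((as.numeric(cfg$seed) * 1009 + epoch) %% 2147483647))
    order <- sample.int(n)
    mom <- momentum_at(epoch, cfg)
    epoch_loss <- 0
    epoch_correct <- 0L
    batch_starts <- seq(1L, n, by = cfg$batch_size)
    for (bs in batch_starts) {
      idx <- order[bs:min(bs + cfg$batch_size - 1L, n)]
      X <- train_set$samples[idx, , , drop = FALSE]
      y <- train_set$labels[idx]
      model$params <- params
      fwd <- model_forward(model, X, keep_cache = TRUE,
                           dropout_keep = model$cfg$dropout_keep)
      loss <- total_loss(fwd$heads, y, head_w)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      }
      grads <- model_backward(model, fwd, y, head_w)
      upd <- sgd_update(params, velocity, grads, cfg$learning_rate, mom,
                        cfg$weight_decay)
      params <- upd$p
      velocity <- upd$v
      epoch_loss <- epoch_loss + loss * length(idx)
      epoch_correct <- epoch_correct +
        sum(max.col(fwd$heads$fused, ties.method = "first") - 1L == y)
      step_count <- step_count + 1L
    }
    model$params <- params
    val_loss <- NA_real_; val_acc <- NA_real_
    if (!is.null(val_set) && n_windows(val_set) > 0) {
      vf <- model_forward(model, val_set$samples)
      val_loss <- total_loss(vf$heads, val_set$labels, head_w)
      val_acc <- mean(max.col(vf$heads$fused, ties.method = "first") - 1L ==
                        val_set$labels)
    }
    hist[[epoch + 1L]] <- tibble::tibble(
      epoch = epoch + 1L, step = step_count,
      train_loss = epoch_loss / n, train_acc = epoch_correct / n,
      val_loss = val_loss, val_acc = val_acc
    )
    if (verbose > 0 && (epoch + 1L) %% verbose == 0) {
      message(sprintf("epoch %d/%d  loss %.4f  acc %.3f", epoch + 1L,
                      cfg$max_epochs, epoch_loss / n, epoch_correct / n))
    }
  }
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 train_cfg = cfg),
            class = "coarsefine_fit")
}

#' @export
print.coarsefine_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("<coarsefine_fit> %d epochs (%d SGD steps)\n", nrow(h),
              last$step))
  cat(sprintf("  final train loss %.4f, accuracy %.3f\n",
              last$train_loss, last$train_acc))
  if (!is.na(last$val_acc)) {
    cat(sprintf("  final validation loss %.4f, accuracy %.3f\n",
                last$val_loss, last$val_acc))
  }
  invisible(x)
}
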