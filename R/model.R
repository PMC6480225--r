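#' Feature-extraction layer specification
#'
#' One feature-extraction (FE) stage of a branch: a 1-D convolution with a
#' rectifier activation followed by max-pooling. Kernel length, strides,
#' pooling geometry and padding mode are all explicit so branch shapes can
#' be reasoned about analytically.
#'
#' @param n_filters Number of convolution filters (output channels).
#' @param kernel_length Convolution kernel length in samples.
#' @param conv_stride Convolution stride.
#' @param pool_size Max-pooling window size.
#' @param pool_stride Max-pooling stride.
#' @param padding `"same"` (default) or `"valid"`, applied to both the
#'   convolution and the pooling.
#' @return A list of class `fe_layer_spec`.
#' @export
fe_layer_spec <- function(n_filters, kernel_length = 2, conv_stride = 1,
                          pool_size = 2, pool_stride = 2,
                          padding = c("same", "valid")) {
  padding <- match.arg(padding)
  vals <- c(n_filters, kernel_length, conv_stride, pool_size, pool_stride)
  if (any(vals < 1) || any(vals != round(vals))) {
    stop("all layer-spec sizes and strides must be integers >= 1",
         call. = FALSE)
  }
  structure(list(n_filters = as.integer(n_filters),
                 kernel_length = as.integer(kernel_length),
                 conv_stride = as.integer(conv_stride),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 padding = padding),
            class = "fe_layer_spec")
}

#' Branch specification
#'
#' A branch is an ordered stack of FE layers. The default architecture has
#' three branches at different temporal granularities: fine (4 layers),
#' medium (2 layers) and coarse (1 layer).
#'
#' @param name Branch name, one of `"fine"`, `"medium"`, `"coarse"`.
#' @param layers List of [fe_layer_spec()] objects.
#' @return A list of class `branch_spec`.
#' @export
branch_spec <- function(name, layers) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, TRUE, "fe_layer_spec")))
  structure(list(name = name, layers = layers), class = "branch_spec")
}

#' Default three-branch coarse-fine configuration
#'
#' Builds the reference architecture for 128-sample, 6-channel windows:
#' * fine: 4 FE layers, filters (18, 18, 36, 36), kernel 2, conv stride 1,
#'   pool 2/stride 2 — halving length per stage, 128 -> 8;
#' * medium: 2 FE layers, filters (18, 36), kernel 2, conv stride 2,
#'   pool 4/stride 2 — 128 -> 8;
#' * coarse: 1 FE layer, 36 filters, kernel 2, conv stride 2, pool
#'   16/stride 8 — 128 -> 8.
#'
#' All padding is "same". Under these conventions every branch emits 8
#' positions of 36 filters, so the fused feature vector entering the
#' classifier has 8 x 36 x 3 = 864 elements. Two stride choices here
#' deviate from a literal reading of the source tables (medium second conv
#' stride 2 rather than 3; coarse pool stride 8 rather than 2): those are
#' the minimal edits under which all three branches reach the published
#' 864-neuron fusion width, which is the one cross-checkable anchor of the
#' architecture. `literal_strides = TRUE` restores the literal strides for
#' sensitivity studies (its fusion width differs from 864).
#'
#' @param input_length Window length in samples (default 128).
#' @param input_channels Sensor channel count (default 6).
#' @param fc_hidden Hidden width of the fully-connected classifier
#'   (default 128).
#' @param n_classes Number of activity classes (default 6).
#' @param dropout_keep Keep-probability of the dropout applied to the fused
#'   feature vector during training (default 0.8).
#' @param aux_head_weights Length-3 weights of the per-branch auxiliary
#'   cross-entropy terms (default all 1).
#' @param kernel_length Convolution kernel length for every layer
#'   (default 2); exposed for the kernel-size sweep.
#' @param literal_strides Use the literal stride table instead of the
#'   864-consistent reconciliation.
#' @return A list of class `coarsefine_config`.
#' @export
default_config <- function(input_length = 128, input_channels = 6,
                           fc_hidden = 128, n_classes = 6,
                           dropout_keep = 0.8,
                           aux_head_weights = c(1, 1, 1),
                           kernel_length = 2,
                           literal_strides = FALSE) {
  k <- kernel_length
  fine <- branch_spec("fine", list(
    fe_layer_spec(18, k, 1, 2, 2),
    fe_layer_spec(18, k, 1, 2, 2),
    fe_layer_spec(36, k, 1, 2, 2),
    fe_layer_spec(36, k, 1, 2, 2)
  ))
  medium <- branch_spec("medium", list(
    fe_layer_spec(18, k, 2, 4, 2),
    fe_layer_spec(36, k, if (literal_strides) 3 else 2, 4, 2)
  ))
  coarse <- branch_spec("coarse", list(
    fe_layer_spec(36, k, 2, 16, if (literal_strides) 2 else 8)
  ))
  coarsefine_config(list(fine, medium, coarse),
                    input_length = input_length,
                    input_channels = input_channels,
                    fc_hidden = fc_hidden, n_classes = n_classes,
                    dropout_keep = dropout_keep,
                    aux_head_weights = aux_head_weights)
}

#' Assemble a full model configuration
#'
#' @param branches List of three [branch_spec()] objects.
#' @inheritParams default_config
#' @return A list of class `coarsefine_config`.
#' @export
coarsefine_config <- function(branches, input_length = 128,
                              input_channels = 6, fc_hidden = 128,
                              n_classes = 6, dropout_keep = 0.8,
                              aux_head_weights = rep(1, length(branches))) {
  stopifnot(all(vapply(branches, inherits, TRUE, "branch_spec")))
  if (dropout_keep <= 0 || dropout_keep > 1) {
    stop("dropout_keep must lie in (0, 1]", call. = FALSE)
  }
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  if (length(aux_head_weights) != length(branches)) {
    stop("need one auxiliary head weight per branch", call. = FALSE)
  }
  structure(list(branches = branches,
                 input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 fc_hidden = as.integer(fc_hidden),
                 n_classes = as.integer(n_classes),
                 dropout_keep = dropout_keep,
                 aux_head_weights = as.numeric(aux_head_weights)),
            class = "coarsefine_config")
}

#' Analytic output length of a branch
#'
#' Walks the shape calculus layer by layer without building the network:
#' same-padded stages map length L to `ceiling(L / stride)`; valid stages
#' to `floor((L - k) / stride) + 1`. Used to validate configurations and as
#' the independent oracle against built models.
#'
#' @param input_length Input window length.
#' @param spec A [branch_spec()].
#' @return Integer output length after the last pooling stage.
#' @examples
#' branch_output_length(128, default_config()$branches[[1]])  # 8
#' @export
branch_output_length <- function(input_length, spec) {
  stopifnot(inherits(spec, "branch_spec"))
  L <- as.integer(input_length)
  if (L < 1) stop("input_length must be >= 1", call. = FALSE)
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    L <- shape_step(L, ly$kernel_length, ly$conv_stride, ly$padding,
                    spec$name, i, "convolution")
    L <- shape_step(L, ly$pool_size, ly$pool_stride, ly$padding,
                    spec$name, i, "pooling")
  }
  L
}

shape_step <- function(L, k, stride, padding, branch, layer, stage) {
  L_out <- if (padding == "same") {
    as.integer(ceiling(L / stride))
  } else {
    as.integer((L - k) %/% stride + 1L)
  }
  if (L_out < 1) {
    stop("shape error: ", branch, " branch layer ", layer, " ", stage,
         " collapses length ", L, " below 1", call. = FALSE)
  }
  L_out
}

#' Length of the fused feature vector
#'
#' Each branch's final pooled output (`output positions x last-layer
#' filters`) is flattened; the fused vector is the concatenation over
#' branches. For the default configuration this is 8 x 36 x 3 = 864.
#'
#' @param cfg A [coarsefine_config()].
#' @return Integer fused feature length.
#' @examples
#' fused_feature_length(default_config())  # 864
#' @export
fused_feature_length <- function(cfg) {
  stopifnot(inherits(cfg, "coarsefine_config"))
  sum(vapply(cfg$branches, function(sp) {
    branch_output_length(cfg$input_length, sp) *
      sp$layers[[length(sp$layers)]]$n_filters
  }, 0L))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build a coarse-fine model
#'
#' Instantiates the three parallel branches on a shared input, the fused
#' classifier head (dropout, rectified hidden layer, linear output,
#' soft-max) and one auxiliary soft-max head per branch on that branch's
#' flattened output. The auxiliary heads contribute cross-entropy terms
#' during training (deep supervision) and are ignored at inference.
#' Weights use seeded He-scaled Gaussian initialization; the same seed
#' always yields the same initial weights.
#'
#' @param cfg A [coarsefine_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `coarsefine_model` with elements `cfg`, `params`
#'   and `seed`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "coarsefine_config"))
  fused <- fused_feature_length(cfg)  # validates all branch shapes
  if (fused < 1) stop("invalid configuration: empty fused vector", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list(branches = list(), aux = list())
  for (bi in seq_along(cfg$branches)) {
    sp <- cfg$branches[[bi]]
    C_in <- cfg$input_channels
    layers <- list()
    for (ly in sp$layers) {
      k <- ly$kernel_length
      layers[[length(layers) + 1L]] <- list(
        W = he_init(c(k, C_in, ly$n_filters), fan_in = k * C_in),
        b = numeric(ly$n_filters)
      )
      C_in <- ly$n_filters
    }
    params$branches[[bi]] <- layers
    flat <- branch_output_length(cfg$input_length, sp) * C_in
    params$aux[[bi]] <- list(
      W = he_init(c(flat, cfg$n_classes), fan_in = flat),
      b = numeric(cfg$n_classes)
    )
  }
  params$fc1 <- list(W = he_init(c(fused, cfg$fc_hidden), fan_in = fused),
                     b = numeric(cfg$fc_hidden))
  params$out <- list(W = he_init(c(cfg$fc_hidden, cfg$n_classes),
                                 fan_in = cfg$fc_hidden),
                     b = numeric(cfg$n_classes))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "coarsefine_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Forward pass over a batch array [B, L, C]. Returns the four head
# probability matrices (fine, medium, coarse, fused) and, when
# keep_cache = TRUE, everything the backward pass needs. dropout_keep < 1
# draws a mask from the current RNG state.
model_forward <- function(model, X, keep_cache = FALSE, dropout_keep = 1) {
  cfg <- model$cfg
  p <- model$params
  B <- dim(X)[1]
  if (dim(X)[2] != cfg$input_length || dim(X)[3] != cfg$input_channels) {
    stop("input shape mismatch: expected [*, ", cfg$input_length, ", ",
         cfg$input_channels, "], got [", paste(dim(X), collapse = ", "),
         "]", call. = FALSE)
  }
  branch_flat <- list()
  branch_caches <- list()
  for (bi in seq_along(cfg$branches)) {
    sp <- cfg$branches[[bi]]
    A <- X
    stages <- list()
    for (li in seq_along(sp$layers)) {
      ly <- sp$layers[[li]]
      pw <- p$branches[[bi]][[li]]
      cv <- conv1d_forward(A, pw$W, pw$b, ly$conv_stride, ly$padding)
      rl <- relu_forward(cv$Y)
      pl <- maxpool1d_forward(rl$Y, ly$pool_size, ly$pool_stride, ly$padding)
      stages[[li]] <- list(conv = cv$cache, relu = rl$cache, pool = pl$cache)
      A <- pl$Y
    }
    flat_dim <- dim(A)[2] * dim(A)[3]
    Aflat <- A
    dim(Aflat) <- c(B, flat_dim)
    branch_flat[[bi]] <- Aflat
    if (keep_cache) {
      branch_caches[[bi]] <- list(stages = stages, out_dim = dim(A))
    }
  }
  fused_vec <- do.call(cbind, branch_flat)
  mask <- if (dropout_keep < 1) dropout_mask(dim(fused_vec), dropout_keep) else NULL
  fused_in <- if (is.null(mask)) fused_vec else fused_vec * mask
  h1 <- dense_forward(fused_in, p$fc1$W, p$fc1$b)
  hr <- relu_forward(h1$Y)
  logits <- dense_forward(hr$Y, p$out$W, p$out$b)
  aux_logits <- lapply(seq_along(cfg$branches), function(bi) {
    dense_forward(branch_flat[[bi]], p$aux[[bi]]$W, p$aux[[bi]]$b)
  })
  heads <- c(lapply(aux_logits, function(a) softmax_rows(a$Y)),
             list(softmax_rows(logits$Y)))
  names(heads) <- c(vapply(cfg$branches, `[[`, "", "name"), "fused")
  out <- list(heads = heads)
  if (keep_cache) {
    out$cache <- list(branches = branch_caches, branch_flat = branch_flat,
                      mask = mask, h1 = h1$cache, hr = hr$cache,
                      logits = logits$cache,
                      aux = lapply(aux_logits, `[[`, "cache"),
                      B = B)
  }
  out
}

# Backward pass from per-head soft-max outputs. dLogits for a weighted
# mean cross-entropy is w * (P - onehot) / B per head. Returns gradients
# with the same nesting as model$params.
model_backward <- function(model, fwd, labels, head_weights) {
  cfg <- model$cfg
  cache <- fwd$cache
  B <- cache$B
  n_branch <- length(cfg$branches)
  onehot <- matrix(0, B, cfg$n_classes)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1

  grads <- list(branches = vector("list", n_branch),
                aux = vector("list", n_branch))

  # fused head
  d_logits <- head_weights[n_branch + 1L] *
    (fwd$heads$fused - onehot) / B
  g_out <- dense_backward(cache$logits, d_logits)
  grads$out <- list(W = g_out$dW, b = g_out$db)
  d_h <- relu_backward(cache$hr, g_out$dX)
  g_fc1 <- dense_backward(cache$h1, d_h)
  grads$fc1 <- list(W = g_fc1$dW, b = g_fc1$db)
  d_fused <- g_fc1$dX
  if (!is.null(cache$mask)) d_fused <- d_fused * cache$mask

  offset <- 0L
  for (bi in seq_len(n_branch)) {
    flat_dim <- ncol(cache$branch_flat[[bi]])
    d_flat <- d_fused[, offset + seq_len(flat_dim), drop = FALSE]
    offset <- offset + flat_dim

    d_aux_logits <- head_weights[bi] * (fwd$heads[[bi]] - onehot) / B
    g_aux <- dense_backward(cache$aux[[bi]], d_aux_logits)
    grads$aux[[bi]] <- list(W = g_aux$dW, b = g_aux$db)
    d_flat <- d_flat + g_aux$dX

    dA <- array(d_flat, dim = cache$branches[[bi]]$out_dim)
    stages <- cache$branches[[bi]]$stages
    layer_grads <- vector("list", length(stages))
    for (li in rev(seq_along(stages))) {
      st <- stages[[li]]
      dA <- maxpool1d_backward(st$pool, dA)$dX
      dA <- relu_backward(st$relu, dA)
      g <- conv1d_backward(st$conv, dA)
      layer_grads[[li]] <- list(W = g$dW, b = g$db)
      dA <- g$dX
    }
    grads$branches[[bi]] <- layer_grads
  }
  grads
}

#' Class probabilities from the fused head
#'
#' @param object A [build_model()] result (class `coarsefine_model`).
#' @param newdata A [har_dataset] or a numeric array
#'   `[n, input_length, input_channels]`.
#' @param ... Unused.
#' @return Numeric matrix `[n, n_classes]` of soft-max probabilities; each
#'   row sums to 1. Predicted class indices are `max.col(...) - 1`.
#' @export
predict.coarsefine_model <- function(object, newdata, ...) {
  nm <- if (inherits(newdata, "har_dataset")) {
    vocab_names(newdata$vocabulary)
  } else NULL
  X <- if (inherits(newdata, "har_dataset")) newdata$samples else newdata
  if (is.matrix(X)) X <- array(X, dim = c(1L, nrow(X), ncol(X)))
  probs <- model_forward(object, X)$heads$fused
  colnames(probs) <- if (!is.null(nm) && length(nm) == ncol(probs)) {
    nm
  } else {
    paste0("class", seq_len(ncol(probs)) - 1L)
  }
  probs
}

#' Predicted class indices (0-based) from the fused head
#' @inheritParams predict.coarsefine_model
#' @param model A `coarsefine_model`.
#' @param dataset A [har_dataset] or array.
#' @return Integer vector of 0-based class indices.
#' @export
predict_classes <- function(model, dataset) {
  max.col(predict(model, dataset), ties.method = "first") - 1L
}

#' @export
print.coarsefine_model <- function(x, ...) {
  cfg <- x$cfg
  cat("<coarsefine_model>\n")
  for (sp in cfg$branches) {
    cat(sprintf("  %s branch: %d FE layer(s), output %d x %d\n",
                sp$name, length(sp$layers),
                branch_output_length(cfg$input_length, sp),
                sp$layers[[length(sp$layers)]]$n_filters))
  }
  cat(sprintf("  fused vector: %d -> hidden %d -> %d classes (dropout keep %.2f)\n",
              fused_feature_length(cfg), cfg$fc_hidden, cfg$n_classes,
              cfg$dropout_keep))
  invisible(x)
}
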