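# Shared fixtures, built in code at test time.

# A small fully-specified configuration that exercises every layer type
# (two-layer branch, strided convs, overlapping pools) but stays cheap.
tiny_config <- function(input_length = 20, input_channels = 2,
                        n_classes = 4, dropout_keep = 1) {
  coarsefine_config(
    list(
      branch_spec("fine", list(fe_layer_spec(3, 2, 1, 2, 2),
                               fe_layer_spec(4, 3, 1, 2, 2))),
      branch_spec("medium", list(fe_layer_spec(3, 2, 2, 4, 2))),
      branch_spec("coarse", list(fe_layer_spec(4, 2, 2, 6, 4)))
    ),
    input_length = input_length, input_channels = input_channels,
    fc_hidden = 7, n_classes = n_classes, dropout_keep = dropout_keep
  )
}

# Random valid single-branch spec plus an input length it accepts.
random_branch_case <- function() {
  n_layers <- sample(1:3, 1)
  layers <- lapply(seq_len(n_layers), function(i) {
    fe_layer_spec(n_filters = sample(1:8, 1),
                  kernel_length = sample(1:4, 1),
                  conv_stride = sample(1:3, 1),
                  pool_size = sample(1:4, 1),
                  pool_stride = sample(1:3, 1),
                  padding = sample(c("same", "valid"), 1))
  })
  spec <- branch_spec("fine", layers)
  for (attempt in 1:20) {
    L <- sample(16:96, 1)
    ok <- tryCatch({branch_output_length(L, spec); TRUE},
                   error = function(e) FALSE)
    if (ok) return(list(spec = spec, input_length = L))
  }
  NULL
}

# Forward-pass output length of a single built branch: the empirical
# counterpart of the analytic shape oracle.
built_branch_length <- function(spec, input_length, input_channels = 2) {
  cfg <- coarsefine_config(list(spec), input_length = input_length,
                           input_channels = input_channels,
                           fc_hidden = 3, n_classes = 2, dropout_keep = 1)
  model <- build_model(cfg, seed = 1)
  X <- array(stats::rnorm(input_length * input_channels),
             c(1, input_length, input_channels))
  flat <- model_forward(model, X, keep_cache = TRUE)$cache
  ncol(flat$branch_flat[[1]]) / spec$layers[[length(spec$layers)]]$n_filters
}

# Central-difference gradient of the multi-head loss w.r.t. selected
# entries of one parameter tensor; independent of the backprop path.
numeric_grad <- function(model, X, y, head_w, get, set, indices,
                         eps = 1e-5) {
  vapply(indices, function(i) {
    mp <- model; v <- get(mp); v[i] <- v[i] + eps; mp <- set(mp, v)
    mm <- model; v <- get(mm); v[i] <- v[i] - eps; mm <- set(mm, v)
    lp <- total_loss(model_forward(mp, X)$heads, y, head_w)
    lm <- total_loss(model_forward(mm, X)$heads, y, head_w)
    (lp - lm) / (2 * eps)
  }, 0)
}

quiet_train <- function(...) suppressWarnings(train(...))
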