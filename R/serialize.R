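# Human-readable (de)serialization of model configurations, and
# checkpointing of trained models with an architecture sidecar.

#' Convert a model configuration to/from a plain list
#'
#' The plain-list form round-trips through YAML or JSON, so architectures
#' can be stored in run configs and checkpoint sidecars.
#'
#' @param cfg A [coarsefine_config()].
#' @return `config_to_list()`: a nested plain list; `config_from_list()`:
#'   a `coarsefine_config`.
#' @export
config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "coarsefine_config"))
  list(
    input_length = cfg$input_length,
    input_channels = cfg$input_channels,
    fc_hidden = cfg$fc_hidden,
    n_classes = cfg$n_classes,
    dropout_keep = cfg$dropout_keep,
    aux_head_weights = cfg$aux_head_weights,
    branches = lapply(cfg$branches, function(sp) {
      list(name = sp$name,
           layers = lapply(sp$layers, function(ly) {
             list(n_filters = ly$n_filters,
                  kernel_length = ly$kernel_length,
                  conv_stride = ly$conv_stride,
                  pool_size = ly$pool_size,
                  pool_stride = ly$pool_stride,
                  padding = ly$padding)
           }))
    })
  )
}

#' @rdname config_to_list
#' @param x A plain list as produced by `config_to_list()`.
#' @export
config_from_list <- function(x) {
  branches <- lapply(x$branches, function(sp) {
    branch_spec(sp$name, lapply(sp$layers, function(ly) {
      fe_layer_spec(ly$n_filters, ly$kernel_length, ly$conv_stride,
                    ly$pool_size, ly$pool_stride, ly$padding)
    }))
  })
  coarsefine_config(branches,
                    input_length = x$input_length,
                    input_channels = x$input_channels,
                    fc_hidden = x$fc_hidden,
                    n_classes = x$n_classes,
                    dropout_keep = x$dropout_keep,
                    aux_head_weights = unlist(x$aux_head_weights))
}

#' Save and load model checkpoints
#'
#' Weights go to an RDS file; the architecture travels alongside as a
#' human-readable JSON sidecar (`<path>.arch.json`) so a checkpoint is
#' self-describing.
#'
#' @param model A `coarsefine_model`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the restored `coarsefine_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "coarsefine_model"))
  saveRDS(list(params = model$params, seed = model$seed), path)
  jsonlite::write_json(config_to_list(model$cfg),
                       paste0(path, ".arch.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  sidecar <- paste0(path, ".arch.json")
  if (!file.exists(path)) stop("missing checkpoint '", path, "'", call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("missing architecture sidecar '", sidecar, "'", call. = FALSE)
  }
  blob <- readRDS(path)
  cfg <- config_from_list(jsonlite::read_json(sidecar, simplifyVector = FALSE))
  structure(list(cfg = cfg, params = blob$params, seed = blob$seed),
            class = "coarsefine_model")
}
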