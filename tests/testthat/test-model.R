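test_that("default architecture matches the reference layer tables", {
  cfg <- default_config()
  fine <- cfg$branches[[1]]; medium <- cfg$branches[[2]]
  coarse <- cfg$branches[[3]]
  expect_equal(length(fine$layers), 4)
  expect_equal(vapply(fine$layers, `[[`, 0L, "n_filters"), c(18L, 18L, 36L, 36L))
  expect_equal(fine$layers[[3]]$n_filters, 36L)
  expect_equal(length(medium$layers), 2)
  expect_equal(vapply(medium$layers, `[[`, 0L, "n_filters"), c(18L, 36L))
  expect_equal(length(coarse$layers), 1)
  expect_equal(coarse$layers[[1]]$pool_size, 16L)
  expect_equal(cfg$dropout_keep, 0.8)
  expect_true(all(vapply(fine$layers, `[[`, "", "padding") == "same"))
})

test_that("shape oracle walks the ceil/floor chain correctly", {
  cfg <- default_config()
  expect_equal(branch_output_length(128, cfg$branches[[1]]), 8L)
  expect_equal(branch_output_length(128, cfg$branches[[2]]), 8L)
  expect_equal(branch_output_length(128, cfg$branches[[3]]), 8L)
  # hand chain for coarse at 64: conv stride 2 -> ceil(64/2)=32,
  # pool stride 8 -> ceil(32/8)=4
  expect_equal(branch_output_length(64, cfg$branches[[3]]), 4L)
  expect_equal(built_branch_length(cfg$branches[[3]], 64, 6), 4)
  # identity layer: kernel 1, all strides 1, pool 1
  ident <- branch_spec("fine", list(fe_layer_spec(2, 1, 1, 1, 1)))
  expect_equal(branch_output_length(10, ident), 10L)
  # collapse raises a shape error naming the layer
  crush <- branch_spec("fine", list(fe_layer_spec(2, 8, 1, 2, 2, "valid"),
                                    fe_layer_spec(2, 8, 4, 2, 2, "valid")))
  expect_error(branch_output_length(9, crush), "layer 2")
})

test_that("fused feature length is the sum of flattened branch outputs", {
  expect_equal(fused_feature_length(default_config()), 864L)
  one <- coarsefine_config(
    list(branch_spec("fine", list(fe_layer_spec(1, 2, 1, 2, 2)))),
    input_length = 2, input_channels = 1, fc_hidden = 2, n_classes = 2)
  expect_equal(fused_feature_length(one), 1L)
  # dual route at input length 256: analytic oracle and forward pass agree
  cfg256 <- default_config(input_length = 256)
  expect_equal(fused_feature_length(cfg256), 1728L)
  m <- build_model(cfg256, seed = 2)
  X <- array(rnorm(256 * 6), c(1, 256, 6))
  fwd <- model_forward(m, X, keep_cache = TRUE)
  expect_equal(ncol(do.call(cbind, fwd$cache$branch_flat)), 1728L)
})

test_that("literal stride tables remain constructible but miss 864", {
  lit <- default_config(literal_strides = TRUE)
  expect_equal(lit$branches[[2]]$layers[[2]]$conv_stride, 3L)
  expect_equal(lit$branches[[3]]$layers[[1]]$pool_stride, 2L)
  expect_false(fused_feature_length(lit) == 864L)
})

test_that("model building is seed-deterministic", {
  cfg <- tiny_config()
  a <- build_model(cfg, seed = 5)
  b <- build_model(cfg, seed = 5)
  c <- build_model(cfg, seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$fc1$W, c$params$fc1$W))
})

test_that("all four heads emit valid probability distributions", {
  m <- build_model(tiny_config(), seed = 3)
  set.seed(1)
  X <- array(rnorm(5 * 20 * 2), c(5, 20, 2))
  heads <- model_forward(m, X)$heads
  expect_length(heads, 4)
  expect_named(heads, c("fine", "medium", "coarse", "fused"))
  for (h in heads) {
    expect_equal(dim(h), c(5, 4))
    expect_true(all(h >= 0))
    expect_lt(max(abs(rowSums(h) - 1)), 1e-6)
  }
})

test_that("soft-max closed forms hold at the fused head", {
  m <- build_model(default_config(), seed = 1)
  # zero the final layer: equal logits -> uniform 1/6
  m$params$out$W[] <- 0
  m$params$out$b[] <- 0
  X <- array(rnorm(128 * 6), c(1, 128, 6))
  p <- predict(m, X)
  expect_lt(max(abs(p - 1 / 6)), 1e-12)
  # logits (1, 0, ..., 0) -> p1 = e / (e + 5)
  m$params$fc1$W[] <- 0
  m$params$fc1$b[] <- 1          # hidden activations all 1
  m$params$out$W[] <- 0
  m$params$out$W[, 1] <- 1 / m$cfg$fc_hidden
  p <- predict(m, X)
  expect_equal(unname(p[1, 1]), exp(1) / (exp(1) + 5), tolerance = 1e-9)
})

test_that("prediction is batched and order-invariant", {
  m <- build_model(tiny_config(), seed = 8)
  set.seed(2)
  X <- array(rnorm(7 * 20 * 2), c(7, 20, 2))
  p <- predict(m, X)
  expect_equal(nrow(p), 7)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  p_perm <- predict(m, X[perm, , , drop = FALSE])
  expect_equal(p_perm, p[perm, ], tolerance = 1e-12)
})

test_that("shape mismatches are reported with expected vs got", {
  m <- build_model(tiny_config(), seed = 1)
  X <- array(rnorm(2 * 19 * 2), c(2, 19, 2))
  expect_error(model_forward(m, X), "expected.*got")
})

test_that("configuration invariants are enforced", {
  expect_error(coarsefine_config(default_config()$branches, dropout_keep = 0),
               "dropout_keep")
  expect_error(coarsefine_config(default_config()$branches, n_classes = 1),
               "n_classes")
  expect_error(fe_layer_spec(0), "integers")
})

test_that("configs round-trip through the plain-list serialization", {
  cfg <- default_config(fc_hidden = 96, dropout_keep = 0.7)
  lst <- config_to_list(cfg)
  expect_equal(config_from_list(lst), cfg)
  # and through YAML text
  path <- withr::local_tempfile()
  yaml::write_yaml(lst, path)
  expect_equal(config_from_list(yaml::read_yaml(path)), cfg)
})

test_that("checkpoints restore models exactly", {
  m <- build_model(tiny_config(), seed = 4)
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".arch.json")))
  back <- load_checkpoint(path)
  set.seed(6)
  X <- array(rnorm(3 * 20 * 2), c(3, 20, 2))
  expect_equal(predict(back, X), predict(m, X))
})
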