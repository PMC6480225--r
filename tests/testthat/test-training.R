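test_that("multi-head loss matches its closed forms", {
  perfect <- matrix(0, 3, 6); perfect[cbind(1:3, c(1, 4, 6))] <- 1
  labels <- c(0L, 3L, 5L)
  expect_equal(total_loss(rep(list(perfect), 4), labels), 0)

  uniform <- matrix(1 / 6, 3, 6)
  expect_equal(total_loss(rep(list(uniform), 4), labels), 4 * log(6),
               tolerance = 1e-9)

  half <- perfect * 0.5 + (1 - perfect) * 0.1
  expect_equal(total_loss(list(perfect, perfect, perfect, half), labels),
               log(2), tolerance = 1e-9)
})

test_that("loss decomposes: weights (0,0,0,1) give fused-head cross-entropy", {
  set.seed(13)
  heads <- replicate(4, {
    p <- matrix(rexp(5 * 6), 5, 6); p / rowSums(p)
  }, simplify = FALSE)
  labels <- sample(0:5, 5, replace = TRUE)
  fused_ce <- mean(-log(heads[[4]][cbind(1:5, labels + 1)]))
  expect_equal(total_loss(heads, labels, weights = c(0, 0, 0, 1)), fused_ce,
               tolerance = 1e-9)
})

test_that("zero probability at the true class is clamped with a warning", {
  p <- matrix(0, 1, 6); p[1, 2] <- 1
  expect_warning(l <- total_loss(list(p), labels = 0L), "clamped")
  expect_true(is.finite(l) && l > 0)
  l4 <- suppressWarnings(total_loss(rep(list(p), 4), labels = 0L))
  expect_equal(l4, 4 * l)
})

test_that("momentum ramps linearly between its bounds", {
  cfg <- training_config()
  expect_equal(momentum_at(0, cfg), 0.5)
  expect_equal(momentum_at(cfg$max_epochs - 1, cfg), 0.99)
  mid <- (cfg$max_epochs - 1) / 2
  expect_equal(momentum_at(mid, cfg), 0.745, tolerance = 1e-9)
  # constant-momentum mode
  const <- training_config(momentum_start = 0.9, momentum_end = 0.9)
  expect_equal(momentum_at(17, const), 0.9)
  expect_error(training_config(momentum_start = 0.9, momentum_end = 0.5),
               "momentum")
  expect_error(training_config(learning_rate = -1), "learning_rate")
})

test_that("backprop matches central-difference gradients on a 2-window batch", {
  m <- build_model(tiny_config(), seed = 11)
  set.seed(5)
  X <- array(rnorm(2 * 20 * 2), c(2, 20, 2))
  y <- c(1L, 3L)
  hw <- c(1, 1, 1, 1)
  fwd <- model_forward(m, X, keep_cache = TRUE)
  grads <- model_backward(m, fwd, y, hw)

  cases <- list(
    list(get = function(m) m$params$out$W,
         set = function(m, v) { m$params$out$W[] <- v; m },
         ana = grads$out$W),
    list(get = function(m) m$params$out$b,
         set = function(m, v) { m$params$out$b[] <- v; m },
         ana = grads$out$b),
    list(get = function(m) m$params$fc1$W,
         set = function(m, v) { m$params$fc1$W[] <- v; m },
         ana = grads$fc1$W),
    list(get = function(m) m$params$aux[[2]]$W,
         set = function(m, v) { m$params$aux[[2]]$W[] <- v; m },
         ana = grads$aux[[2]]$W),
    list(get = function(m) m$params$branches[[1]][[1]]$W,
         set = function(m, v) { m$params$branches[[1]][[1]]$W[] <- v; m },
         ana = grads$branches[[1]][[1]]$W)
  )
  set.seed(7)
  for (case in cases) {
    idx <- sample(length(case$get(m)), min(6, length(case$get(m))))
    num <- numeric_grad(m, X, y, hw, case$get, case$set, idx)
    ana <- case$ana[idx]
    rel <- abs(num - ana) / pmax(abs(num) + abs(ana), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training history bookkeeping and determinism hold", {
  d <- generate_dataset(10, default_specs("uci"), seed = 21,
                        window_samples = 32)
  cfg <- default_config(input_length = 32, fc_hidden = 16)
  tc <- quick_training_config(max_epochs = 2, batch_size = 16, seed = 9)
  fit1 <- quiet_train(build_model(cfg, seed = 9), d, tc)
  expect_equal(nrow(fit1$history), 2)
  expect_equal(fit1$history$epoch, 1:2)
  expect_true(all(fit1$history$train_loss >= 0))
  # 60 windows, batch 16 -> 4 steps/epoch, incomplete last batch used
  expect_equal(fit1$history$step, c(4L, 8L))

  fit2 <- quiet_train(build_model(cfg, seed = 9), d, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)

  fit3 <- quiet_train(build_model(cfg, seed = 10), d,
                      quick_training_config(max_epochs = 2, batch_size = 16,
                                            seed = 10))
  expect_false(identical(fit1$history$train_loss, fit3$history$train_loss))
})

test_that("SGD drives the loss down on separable synthetic data", {
  d <- generate_dataset(20, default_specs("uci"), seed = 33,
                        window_samples = 64)
  sp <- protocol_split(d, "subject_independent", 0.7, seed = 33)
  std <- standardize(sp$train)
  cfg <- default_config(input_length = 64)
  fit <- quiet_train(build_model(cfg, seed = 33), std$dataset,
                     quick_training_config(max_epochs = 40, seed = 33))
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], 0.05 * h$train_loss[1])
  expect_gte(h$train_acc[nrow(h)], 0.95)
})

test_that("weight decay and validation tracking behave as configured", {
  d <- generate_dataset(4, default_specs("uci"), seed = 3,
                        window_samples = 32)
  cfg <- default_config(input_length = 32, fc_hidden = 8)
  tc <- quick_training_config(max_epochs = 3, validation_fraction = 0.25,
                              seed = 4)
  fit <- quiet_train(build_model(cfg, seed = 4), d, tc)
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(fit$history$val_acc >= 0 & fit$history$val_acc <= 1))

  # decay shrinks weights relative to a decay-free run
  tc0 <- quick_training_config(max_epochs = 3, weight_decay = 0, seed = 4)
  tc1 <- quick_training_config(max_epochs = 3, weight_decay = 0.5, seed = 4)
  f0 <- quiet_train(build_model(cfg, seed = 4), d, tc0)
  f1 <- quiet_train(build_model(cfg, seed = 4), d, tc1)
  expect_lt(sum(f1$model$params$fc1$W^2), sum(f0$model$params$fc1$W^2))
})
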