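# The 3D residual network: shape arithmetic, splits, gradients, training
# behaviour, the freeze contract, and cross-validated prediction.

test_that("convolutional shape arithmetic matches the ceil-halving chain", {
  sp <- network_spec(c(121, 145, 121))
  expect_identical(sp$conv_shapes[[5]], c(4L, 5L, 4L))
  expect_identical(sp$block_channels[5], 128L)
  expect_identical(sp$flat_dim, 4L * 5L * 4L * 128L)
  expect_identical(sp$embedding_dim, 256L)

  sp32 <- network_spec(c(32, 32, 32))
  expect_identical(sp32$conv_shapes[[5]], c(1L, 1L, 1L))
  sp24 <- network_spec(c(24, 28, 24))
  expect_identical(lapply(sp24$conv_shapes, `[`, 1),
                   list(12L, 6L, 3L, 2L, 1L))   # 24->12->6->3->2->1

  # property: 50 random shapes against a brute-force halving loop
  set.seed(1)
  for (i in 1:50) {
    shp <- sample(8:128, 3, replace = TRUE)
    k <- sample(1:4, 1)
    sp <- network_spec(shp, n_blocks = k,
                       block_channels = rep(4L, k))
    brute <- shp
    for (j in seq_len(k)) brute <- ceiling(brute / 2)
    expect_identical(sp$conv_shapes[[k]], as.integer(brute))
  }
  expect_error(network_spec(c(4, 4, 4)), "too small")
})

test_that("60/20/20 split uses floor/floor/remainder arithmetic", {
  sp <- split_cohort(1481, seed = 1)
  expect_identical(lengths(sp[c("train", "val", "test")]),
                   c(train = 888L, val = 296L, test = 297L))
  expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:1481)
  sp10 <- split_cohort(10, seed = 2)
  expect_identical(lengths(sp10[c("train", "val", "test")]),
                   c(train = 6L, val = 2L, test = 2L))
  sp101 <- split_cohort(101, seed = 3)
  expect_identical(lengths(sp101[c("train", "val", "test")]),
                   c(train = 60L, val = 20L, test = 21L))
  expect_error(split_cohort(100, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("k-fold assignment is balanced, disjoint and exhaustive", {
  f <- make_folds(77, 5, seed = 1)
  expect_identical(as.integer(sort(table(f), decreasing = TRUE)),
                   c(16L, 16L, 15L, 15L, 15L))
  expect_identical(sort(unique(f)), 1:5)
  loo <- make_folds(6, 6, seed = 1)
  expect_identical(as.integer(sort(table(loo))), rep(1L, 6))
  expect_error(make_folds(4, 5), "2..n")
})

test_that("analytic gradients match finite differences", {
  spec <- network_spec(c(8, 9, 8), n_blocks = 2L, block_channels = c(2L, 3L),
                       embedding_dim = 4L, batch_size = 2L)
  model <- build_network(spec, seed = 42)
  set.seed(7)
  B <- 3L
  vols <- lapply(1:B, function(i) array(runif(prod(spec$input_shape)),
                                        spec$input_shape))
  ages <- c(55, 70, 62)
  X <- brainfuse:::stack_volumes(vols, 1:B)
  fwd <- brainfuse:::net_forward(model, X, B, train = TRUE, keep_cache = TRUE)
  g <- brainfuse:::net_backward(model, fwd, sign(fwd$pred - ages) / B, B,
                                trainable = "all")
  loss_fn <- function(m) {
    f <- brainfuse:::net_forward(m, X, B, train = TRUE)
    mean(abs(f$pred - ages))
  }
  eps <- 1e-6
  set.seed(8)
  for (nm in names(g)) {
    if (startsWith(nm, ".")) next
    for (i in sample(length(g[[nm]]), min(3L, length(g[[nm]])))) {
      m2 <- model; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- model; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d/d %s[%d]", nm, i))
    }
  }
})

test_that("training learns: validation MAE beats the mean-age baseline", {
  coh <- tiny_cohort(n = 100, seed = 11)
  sc <- scale_volumes(coh$volumes)
  spec <- small_netspec()
  model <- build_network(spec, seed = 1)
  plan <- split_cohort(100, seed = 2)
  fit <- pretrain(model, sc$volumes, coh$subjects$age, plan, epochs = 8,
                  seed = 3)
  ages <- coh$subjects$age
  baseline <- mean(abs(mean(ages[plan$train]) - ages[plan$val]))
  best_val <- min(fit$history$val_mae)
  expect_lt(best_val, baseline)
  expect_equal(nrow(fit$history), 8)
  expect_identical(fit$provenance, "pretrained")
})

test_that("zero-epoch training returns the initialization unchanged", {
  coh <- tiny_cohort(n = 10, pairs = 2L, grid = c(12L, 12L, 12L), seed = 4)
  sc <- scale_volumes(coh$volumes)
  spec <- small_netspec(grid = c(12L, 12L, 12L), n_blocks = 3L,
                        widths = c(2L, 4L, 4L))
  model <- build_network(spec, seed = 9)
  plan <- split_cohort(10, seed = 1)
  fit <- pretrain(model, sc$volumes, coh$subjects$age, plan, epochs = 0)
  expect_identical(fit$params, model$params)
  ft <- fine_tune(model, sc$volumes, coh$subjects$age, epochs = 0)
  expect_identical(ft$params, model$params)
})

test_that("identical seeds give identical training trajectories", {
  coh <- tiny_cohort(n = 24, pairs = 2L, grid = c(12L, 12L, 12L), seed = 4)
  sc <- scale_volumes(coh$volumes)
  spec <- small_netspec(grid = c(12L, 12L, 12L), n_blocks = 3L,
                        widths = c(2L, 4L, 4L))
  plan <- split_cohort(24, seed = 1)
  f1 <- pretrain(build_network(spec, seed = 9), sc$volumes, coh$subjects$age,
                 plan, epochs = 3, seed = 5)
  f2 <- pretrain(build_network(spec, seed = 9), sc$volumes, coh$subjects$age,
                 plan, epochs = 3, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$best_epoch, f2$best_epoch)
  expect_identical(f1$history, f2$history)
})

test_that("fine-tuning freezes every convolutional tensor exactly", {
  coh <- tiny_cohort(n = 30, pairs = 2L, grid = c(12L, 12L, 12L), seed = 6)
  sc <- scale_volumes(coh$volumes)
  spec <- small_netspec(grid = c(12L, 12L, 12L), n_blocks = 3L,
                        widths = c(2L, 4L, 4L))
  plan <- split_cohort(30, seed = 1)
  pre <- pretrain(build_network(spec, seed = 2), sc$volumes,
                  coh$subjects$age, plan, epochs = 2, seed = 3)
  ft <- fine_tune(pre, sc$volumes, coh$subjects$age, epochs = 4, seed = 4)
  conv_keys <- names(pre$params)[!startsWith(names(pre$params), "fc")]
  fc_keys <- setdiff(names(pre$params), conv_keys)
  expect_gt(length(conv_keys), 0)
  for (nm in conv_keys) {
    expect_identical(ft$params[[nm]], pre$params[[nm]])
  }
  expect_false(all(vapply(fc_keys, function(nm) {
    identical(ft$params[[nm]], pre$params[[nm]])
  }, logical(1))))
  expect_identical(ft$bn, pre$bn)      # running stats frozen too
  expect_identical(ft$provenance, "finetuned")
})

test_that("weight loading validates layer shapes and names the offender", {
  spec_a <- small_netspec(grid = c(12L, 12L, 12L), n_blocks = 3L,
                          widths = c(2L, 4L, 4L))
  spec_b <- small_netspec(grid = c(12L, 12L, 12L), n_blocks = 3L,
                          widths = c(2L, 4L, 8L))
  ma <- build_network(spec_a, seed = 1)
  mb <- build_network(spec_b, seed = 1)
  expect_error(load_weights(ma, mb), "block3")
  mc <- load_weights(ma, build_network(spec_a, seed = 5))
  expect_identical(mc$params, build_network(spec_a, seed = 5)$params)
})

test_that("embeddings are deterministic and compose to the prediction", {
  coh <- tiny_cohort(n = 6, pairs = 2L, grid = c(12L, 12L, 12L), seed = 8)
  sc <- scale_volumes(coh$volumes)
  spec <- small_netspec(grid = c(12L, 12L, 12L), n_blocks = 3L,
                        widths = c(2L, 4L, 4L), embedding = 16L)
  model <- build_network(spec, seed = 3)
  H <- extract_features(model, sc$volumes)
  expect_identical(dim(H), c(6L, 16L))
  expect_identical(H, extract_features(model, sc$volumes))
  composed <- drop(H %*% model$params[["fc2.W"]] + model$params[["fc2.b"]])
  expect_equal(composed, predict_ages(model, sc$volumes), tolerance = 1e-12)
  # default spec gives a 256-dimensional embedding
  expect_identical(network_spec(c(121, 145, 121))$embedding_dim, 256L)
})

test_that("cross-validated prediction is a partition with recorded folds", {
  set.seed(1)
  X <- matrix(rnorm(77 * 3), 77, 3)
  ages <- 50 + 10 * X[, 1] + rnorm(77, 0, 0.1)
  ps <- crossval_predict(function(Xtr, ytr, s) {
    fit <- lm.fit(cbind(1, Xtr), ytr)
    function(Z) drop(cbind(1, Z) %*% fit$coefficients)
  }, X, ages, k = 5, seed = 2)
  expect_identical(nrow(ps), 77L)
  expect_identical(as.integer(sort(table(ps$fold), decreasing = TRUE)),
                   c(16L, 16L, 15L, 15L, 15L))
  expect_lt(mae(ps), 1)
  expect_identical(ps$error, ps$predicted - ps$chronological)
})
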