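test_that("logistic regression solves a separable low-dimensional problem", {
  ds <- gauss_dataset(n_per_class = 15, n_points = 4, shift = 3, seed = 1)
  fit <- suppressWarnings(train_lr(ds))
  pr <- predict(fit, ds)
  expect_equal(mean(pr$.pred == ds$label), 1)
  expect_true(all(pr$.prob > 0 & pr$.prob < 1))
  # HFO rows have positive means, so the fitted direction points positive
  expect_gt(sum(fit$beta[-1]), 0)
  expect_s3_class(fit, "hfo_lr")
})

test_that("logistic regression recovers known coefficients on glm-sized data", {
  set.seed(5)
  n <- 400
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  p <- plogis(0.5 + 1.5 * x1 - 2 * x2)
  y <- rbinom(n, 1, p)
  ds <- segment_dataset(cbind(x1, x2),
                        label = ifelse(y == 1, "HFO", "NC"), fs = 2400)
  fit <- train_lr(ds)
  ref <- stats::glm(y ~ x1 + x2, family = binomial())
  expect_equal(as.numeric(fit$beta), as.numeric(stats::coef(ref)),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("rank-deficient logistic fits still predict, with zeroed NA terms", {
  ds <- tiny_dataset(6, 6, n_points = 200, seed = 2) |> preprocess_segments()
  fit <- suppressWarnings(train_lr(ds))
  expect_false(anyNA(fit$beta))
  pr <- predict(fit, ds)
  expect_identical(nrow(pr), 12L)
  expect_true(all(is.finite(pr$.prob)))
})

test_that("the attention-free variant carries dense sublayers, not attention", {
  ds <- tiny_dataset(6, 6, seed = 3) |> preprocess_segments()
  spec <- resden_spec(transhfo_config(n_layers = 2, n_heads = 2, d_model = 16,
                                      frame_width = 20, dense_units = c(8, 1),
                                      ffn_width = 32),
                      train_config(epochs = 1))
  fit <- train_detector(spec, ds, seed = 1)
  for (lp in fit$params$layers) {
    expect_false(any(c("Wq", "Wk", "Wv", "Wo") %in% names(lp)))
    expect_true(all(c("Wr1", "br1", "Wr2", "br2") %in% names(lp)))
    expect_identical(dim(lp$Wr1), c(16L, 128L))
    expect_identical(dim(lp$Wr2), c(128L, 16L))
  }
  pr <- predict(fit, ds)
  expect_true(all(pr$.prob > 0 & pr$.prob < 1))
  expect_identical(pr, predict(fit, ds))
})

test_that("forcing the dense sublayer cannot be overridden by the config", {
  spec <- resden_spec(transhfo_config(sublayer = "attention"))
  expect_identical(spec$config$sublayer, "dense")
})

test_that("all detector specs share one train/predict interface", {
  ds <- gauss_dataset(n_per_class = 10, n_points = 20, seed = 4)
  specs <- list(
    transhfo_spec(tiny_config(frame_width = 5), train_config(epochs = 1)),
    resden_spec(tiny_config(frame_width = 5), train_config(epochs = 1)),
    lr_spec(),
    ssae_spec(ssae_config(hidden_sizes = c(8, 8),
                          pretrain_epochs = 2, finetune_epochs = 2))
  )
  for (spec in specs) {
    fit <- suppressWarnings(train_detector(spec, ds, seed = 1))
    pr <- predict(fit, ds)
    expect_named(pr, c(".prob", ".pred"))
    expect_identical(nrow(pr), nrow(ds))
    expect_true(all(pr$.pred %in% c("HFO", "NC")))
  }
})

test_that("the autoencoder stack has the configured hidden widths", {
  ds <- gauss_dataset(n_per_class = 12, n_points = 40, seed = 6)
  cfg <- ssae_config(pretrain_epochs = 2, finetune_epochs = 3, seed = 1)
  fit <- train_ssae(ds, cfg)
  expect_length(fit$enc, 3)
  expect_identical(dim(fit$enc[[1]]$W), c(40L, 30L))
  expect_identical(dim(fit$enc[[2]]$W), c(30L, 30L))
  expect_identical(dim(fit$enc[[3]]$W), c(30L, 30L))
  expect_identical(dim(fit$w_out), c(30L, 1L))
  expect_length(fit$pretrain_history, 3)
  expect_true(all(lengths(fit$pretrain_history) == 2))
})

test_that("autoencoder pre-training reduces reconstruction error", {
  ds <- gauss_dataset(n_per_class = 20, n_points = 30, shift = 1, seed = 7)
  cfg <- ssae_config(hidden_sizes = 10, pretrain_epochs = 12,
                     finetune_epochs = 1, seed = 2)
  fit <- train_ssae(ds, cfg)
  h <- fit$pretrain_history[[1]]
  expect_lt(tail(h, 1), h[1])
})

test_that("the sparsity penalty vanishes exactly at the target activation", {
  expect_equal(kl_sparsity(0.1, rep(0.1, 30)), 0, tolerance = 1e-12)
  expect_gt(kl_sparsity(0.1, rep(0.5, 30)), 0)
  expect_gt(kl_sparsity(0.3, c(0.1, 0.3, 0.9)), 0)
  # symmetric in the deviation direction only through positivity
  expect_true(is.finite(kl_sparsity(0.1, c(0, 1))))
})

test_that("fine-tuning stops early on a flat validation loss", {
  ds <- gauss_dataset(n_per_class = 10, n_points = 10, seed = 8)
  cfg <- ssae_config(hidden_sizes = 5, pretrain_epochs = 1,
                     finetune_epochs = 25, learning_rate = 0,
                     early_stop_patience = 3, seed = 3)
  fit <- train_ssae(ds, cfg)
  # zero learning rate makes every validation loss identical
  expect_lte(length(fit$val_history), 4 + cfg$early_stop_patience)
})

test_that("SSAE training is deterministic in its seed", {
  ds <- gauss_dataset(n_per_class = 8, n_points = 12, seed = 9)
  cfg <- ssae_config(hidden_sizes = 6, pretrain_epochs = 2,
                     finetune_epochs = 2, seed = 11)
  f1 <- train_ssae(ds, cfg)
  f2 <- train_ssae(ds, cfg)
  expect_identical(predict(f1, ds), predict(f2, ds))
})

test_that("hyperparameter selection returns a config from the grid", {
  ds <- gauss_dataset(n_per_class = 10, n_points = 8, seed = 10)
  sel <- select_ssae_hyperparams(
    ds, sparsity_grid = c(0.1, 0.3), l2_grid = c(0.1),
    cfg = ssae_config(hidden_sizes = 4, pretrain_epochs = 1,
                      finetune_epochs = 2),
    seed = 1)
  expect_identical(nrow(sel$results), 2L)
  expect_true(sel$config$sparsity_proportion %in% c(0.1, 0.3))
  expect_identical(sel$config$l2_weight, 0.1)
})
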