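test_that("framing tiles the segment into contiguous tokens", {
  x <- seq_len(2000)
  Fr <- frame_tokens(x, 20)
  expect_identical(dim(Fr), c(100L, 20L))
  expect_equal(as.vector(t(Fr)), x)
  expect_equal(Fr[4, ], x[61:80])  # token with 0-based index 3
  expect_error(frame_tokens(seq_len(2000), 23), "divide")
})

test_that("attention weights are a row-stochastic convex combination", {
  out <- scaled_attention(diag(2), diag(2), diag(2))
  expect_equal(as.numeric(out[1, ]), c(0.6698, 0.3302), tolerance = 1e-4)
  expect_equal(as.numeric(out[2, ]), c(0.3302, 0.6698), tolerance = 1e-4)
  A <- attr(out, "weights")
  expect_equal(rowSums(A), c(1, 1), tolerance = 1e-12)
  V <- matrix(rnorm(12), 4, 3)
  one <- scaled_attention(matrix(rnorm(2), 1), matrix(rnorm(2), 1),
                          V[1, , drop = FALSE])
  expect_equal(as.numeric(one), V[1, ], tolerance = 1e-12)
  unif <- scaled_attention(matrix(0, 4, 2), matrix(rnorm(8), 4, 2), V)
  expect_equal(unif[1, ], colMeans(V), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("attention matches a from-scratch softmax oracle on random inputs", {
  for (s in 1:25) {
    Q <- withr::with_seed(s, matrix(rnorm(20), 5, 4))
    K <- withr::with_seed(s + 100, matrix(rnorm(20), 5, 4))
    V <- withr::with_seed(s + 200, matrix(rnorm(15), 5, 3))
    got <- scaled_attention(Q, K, V)
    S <- Q %*% t(K) / sqrt(4)
    oracle <- matrix(0, 5, 3)
    for (i in 1:5) {
      e <- exp(S[i, ] - max(S[i, ]))
      oracle[i, ] <- (e / sum(e)) %*% V
    }
    expect_lt(max(abs(got - oracle)), 1e-6)
    expect_lt(max(abs(rowSums(attr(got, "weights")) - 1)), 1e-6)
  }
})

test_that("the linear_d variant scales scores by d_k instead of sqrt(d_k)", {
  Q <- matrix(rnorm(8), 2, 4)
  K <- matrix(rnorm(8), 2, 4)
  V <- matrix(rnorm(8), 2, 4)
  lin <- scaled_attention(Q, K, V, scale = "linear_d")
  manual <- softmax_rows(Q %*% t(K) / 4) %*% V
  expect_equal(lin, manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("multi-head attention equals a per-head loop over column blocks", {
  for (h in c(1L, 2L, 4L)) {
    d <- 8L
    dk <- d %/% h
    set.seed(h)
    X <- matrix(rnorm(40), 5, d)
    Wq <- matrix(rnorm(d * d), d) / sqrt(d)
    Wk <- matrix(rnorm(d * d), d) / sqrt(d)
    Wv <- matrix(rnorm(d * d), d) / sqrt(d)
    Wo <- matrix(rnorm(d * d), d) / sqrt(d)
    got <- multi_head_attention(X, Wq, Wk, Wv, Wo, n_heads = h)
    expect_identical(dim(got), c(5L, d))
    H <- matrix(0, 5, d)
    for (j in seq_len(h)) {
      cols <- ((j - 1) * dk + 1):(j * dk)
      H[, cols] <- scaled_attention((X %*% Wq)[, cols, drop = FALSE],
                                    (X %*% Wk)[, cols, drop = FALSE],
                                    (X %*% Wv)[, cols, drop = FALSE])
    }
    expect_lt(max(abs(got - H %*% Wo)), 1e-6)
  }
})

test_that("the batched internal sublayer equals per-sample exported attention", {
  config <- tiny_config()
  d <- config$d_model
  set.seed(11)
  lp <- init_transhfo_params(config, 500)$layers[[1]]
  n <- 6L
  B <- 3L
  X <- matrix(rnorm(B * n * d), B * n, d)
  batched <- attention_sublayer_fwd(X, lp, config, B = B, n = n)$out
  for (b in seq_len(B)) {
    idx <- ((b - 1) * n + 1):(b * n)
    solo <- multi_head_attention(X[idx, ], lp$Wq, lp$Wk, lp$Wv, lp$Wo,
                                 n_heads = config$n_heads)
    expect_lt(max(abs(batched[idx, ] - solo)), 1e-6)
  }
})

test_that("layer normalization standardizes every row", {
  X <- matrix(rnorm(60, mean = 5, sd = 4), 6, 10)
  Z <- layer_norm(X)
  expect_equal(rowMeans(Z), rep(0, 6), tolerance = 1e-10)
  expect_equal(apply(Z, 1, function(r) mean(r^2)), rep(1, 6),
               tolerance = 1e-4)
  gain <- runif(10, 0.5, 2)
  bias <- rnorm(10)
  Za <- layer_norm(X, gain, bias)
  expect_equal(Za, sweep(sweep(Z, 2, gain, "*"), 2, bias, "+"),
               tolerance = 1e-12)
})

test_that("a zero sublayer isolates the residual path of the wrapper", {
  X <- matrix(rnorm(40), 5, 8)
  expect_equal(residual_norm(X, 0), layer_norm(pmax(X, 0)),
               tolerance = 1e-12)
  expect_equal(residual_norm(X, 0, norm = "postnorm"), layer_norm(X),
               tolerance = 1e-12)
  S <- matrix(rnorm(40), 5, 8)
  expect_equal(residual_norm(X, S), layer_norm(pmax(X + S, 0)),
               tolerance = 1e-12)
})

test_that("a block composes exported attention, wrapper and feed-forward", {
  config <- tiny_config(n_layers = 1)
  set.seed(21)
  params <- init_transhfo_params(config, 500)
  lp <- params$layers[[1]]
  X <- matrix(rnorm(25 * config$d_model), 25, config$d_model)
  att <- multi_head_attention(X, lp$Wq, lp$Wk, lp$Wv, lp$Wo,
                              n_heads = config$n_heads)
  z1 <- residual_norm(X, att, lp$g1, lp$be1)
  ff <- sweep(pmax(sweep(z1 %*% lp$W1, 2, lp$b1, "+"), 0) %*% lp$W2,
              2, lp$b2, "+")
  expected <- residual_norm(z1, ff, lp$g2, lp$be2)
  expect_equal(transformer_layer(X, lp, config), expected, tolerance = 1e-10)
})

test_that("the dense head computes the advertised affine-ReLU chain", {
  head <- list(list(W = diag(2), b = c(0, 0)),
               list(W = matrix(c(2, 3), 2, 1), b = 1))
  hf <- head_fwd(matrix(c(1, -1), 1, 2), head)
  # ReLU((1, -1)) = (1, 0); 2 * 1 + 3 * 0 + 1 = 3
  expect_equal(as.numeric(hf$logit), 3, tolerance = 1e-12)
  expect_equal(hf$prob, plogis(3), tolerance = 1e-12)
  zeroed <- list(list(W = matrix(0, 2, 1), b = 0))
  expect_equal(head_fwd(matrix(rnorm(2), 1, 2), zeroed)$prob, 0.5)
})

test_that("binary cross-entropy takes its closed-form values", {
  expect_equal(cross_entropy_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(0, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(1, 1), -log(1 - 1e-7), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(1, 0), -log(1e-7), tolerance = 1e-9)
  expect_true(is.finite(cross_entropy_loss(c(1, 0), c(0, 1))))
  expect_equal(cross_entropy_loss(c("HFO", "NC"), c(0.5, 0.5)), log(2),
               tolerance = 1e-12)
})

test_that("the loss equals a brute-force per-sample sum on random batches", {
  for (s in 1:5) {
    y <- withr::with_seed(s, rbinom(16, 1, 0.5))
    p <- withr::with_seed(s + 50, runif(16, 0.01, 0.99))
    manual <- 0
    for (i in 1:16) {
      manual <- manual - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
    }
    expect_lt(abs(cross_entropy_loss(y, p) - manual / 16), 1e-6)
  }
})

test_that("analytic gradients match central finite differences", {
  config <- transhfo_config(n_layers = 2, n_heads = 2, d_model = 8,
                            frame_width = 8, dropout = 0,
                            dense_units = c(6, 3, 1), ffn_width = 12)
  set.seed(33)
  params <- init_transhfo_params(config, 40)
  Xmat <- matrix(rnorm(3 * 40), 3, 40)
  y <- c(1, 0, 1)
  theta <- flatten_params(params)
  skel <- params
  g <- flatten_params(model_loss_grad(unflatten_params(theta, skel), config,
                                      Xmat, y, training = FALSE)$grads)
  eps <- 1e-5
  coords <- withr::with_seed(1, sample.int(length(theta), 80))
  for (i in coords) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    fd <- (model_loss_grad(unflatten_params(tp, skel), config, Xmat, y,
                           training = FALSE)$loss -
           model_loss_grad(unflatten_params(tm, skel), config, Xmat, y,
                           training = FALSE)$loss) / (2 * eps)
    expect_lt(abs(fd - g[i]), 1e-6 * max(1, abs(fd)))
  }
})

test_that("training runs the configured number of epochs and is reproducible", {
  ds <- tiny_dataset(8, 8, seed = 50) |> preprocess_segments()
  cfg <- tiny_config()
  fit1 <- train_transhfo(ds, cfg, train_config(epochs = 3, seed = 2))
  fit2 <- train_transhfo(ds, cfg, train_config(epochs = 3, seed = 2))
  expect_length(fit1$history, 3)
  expect_identical(fit1$params, fit2$params)
  p1 <- predict(fit1, ds)
  p2 <- predict(fit2, ds)
  expect_identical(p1, p2)
  expect_true(all(p1$.prob > 0 & p1$.prob < 1))
  expect_true(all(p1$.pred %in% c("HFO", "NC")))
  fit3 <- train_transhfo(ds, cfg, train_config(epochs = 3, seed = 3))
  expect_false(identical(fit1$params, fit3$params))
})

test_that("training reduces the loss on clearly separable data", {
  for (s in 1:3) {
    ds <- tiny_dataset(12, 12, amplitude = 6, seed = 60 + s) |>
      preprocess_segments()
    fit <- train_transhfo(ds, tiny_config(),
                          train_config(epochs = 8, seed = s))
    expect_lt(tail(fit$history, 1), fit$history[1])
  }
})

test_that("training rejects unlabelled or single-class data", {
  ds <- tiny_dataset(6, 6, seed = 70)
  ds_un <- ds
  ds_un$label[1] <- "UNLABELED"
  expect_error(train_transhfo(ds_un, tiny_config()), "labelled")
  expect_error(train_transhfo(ds[ds$label == "HFO", ], tiny_config()),
               "both classes")
  expect_error(train_transhfo(ds, transhfo_config(frame_width = 23)),
               "divide")
})

test_that("a zeroed final head yields indifferent 0.5 probabilities", {
  ds <- tiny_dataset(6, 6, seed = 71) |> preprocess_segments()
  fit <- train_transhfo(ds, tiny_config(), train_config(epochs = 1, seed = 1))
  m <- length(fit$params$head)
  fit$params$head[[m]]$W[] <- 0
  fit$params$head[[m]]$b[] <- 0
  expect_equal(predict(fit, ds)$.prob, rep(0.5, 12), tolerance = 1e-12)
})
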