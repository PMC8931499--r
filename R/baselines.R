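#' Detector specifications
#'
#' Lightweight spec objects giving all four detectors one interface, so the
#' evaluation machinery treats them interchangeably:
#' [train_detector()] fits a spec to a labelled segment dataset and the
#' fitted model's `predict()` method returns a tibble of `.prob` and
#' `.pred`.
#'
#' * `transhfo_spec()` - the attention classifier ([train_transhfo()]).
#' * `resden_spec()` - the attention-free variant: the multi-head attention
#'   sublayer is replaced by a position-wise 128-unit ReLU dense map (plus a
#'   linear projection back to the token width, required by the residual
#'   connection); everything else is identical.
#' * `lr_spec()` - maximum-likelihood logistic regression on flattened
#'   segments.
#' * `ssae_spec()` - the stacked sparse autoencoder detector.
#'
#' @param config,tconfig Model / training configuration for the network
#'   detectors.
#' @param ridge Optional ridge penalty for the logistic baseline (0 = pure
#'   maximum likelihood).
#' @param ssae_config An [ssae_config()] for the SSAE detector.
#' @return An object of class `detector_spec`.
#' @name detector_spec
NULL

#' @rdname detector_spec
#' @export
transhfo_spec <- function(config = transhfo_config(),
                          tconfig = train_config()) {
  structure(list(config = config, tconfig = tconfig, label = "TransHFO"),
            class = c("transhfo_spec", "detector_spec"))
}

#' @rdname detector_spec
#' @export
resden_spec <- function(config = transhfo_config(sublayer = "dense"),
                        tconfig = train_config()) {
  config$sublayer <- "dense"
  structure(list(config = config, tconfig = tconfig, label = "ResDen"),
            class = c("resden_spec", "detector_spec"))
}

#' @rdname detector_spec
#' @export
lr_spec <- function(ridge = 0) {
  structure(list(ridge = ridge, label = "LR"),
            class = c("lr_spec", "detector_spec"))
}

#' @rdname detector_spec
#' @export
ssae_spec <- function(ssae_config = ssae_config()) {
  structure(list(config = ssae_config, label = "SMO"),
            class = c("ssae_spec", "detector_spec"))
}

#' Fit a detector spec to labelled segments
#'
#' @param spec A `detector_spec` (see [transhfo_spec()] and friends).
#' @param data A labelled segment dataset tibble.
#' @param seed Optional integer seed overriding the spec's own.
#' @return A fitted model whose `predict()` method returns a tibble with
#'   `.prob` and `.pred` columns.
#' @export
train_detector <- function(spec, data, seed = NULL) {
  UseMethod("train_detector")
}

#' @export
train_detector.transhfo_spec <- function(spec, data, seed = NULL) {
  tcfg <- spec$tconfig
  if (!is.null(seed)) tcfg$seed <- seed
  train_transhfo(data, spec$config, tcfg)
}

#' @export
train_detector.resden_spec <- train_detector.transhfo_spec

#' @export
train_detector.lr_spec <- function(spec, data, seed = NULL) {
  train_lr(data, ridge = spec$ridge)
}

#' @export
train_detector.ssae_spec <- function(spec, data, seed = NULL) {
  cfg <- spec$config
  if (!is.null(seed)) cfg$seed <- seed
  train_ssae(data, cfg)
}

# ---- logistic regression --------------------------------------------------

#' Logistic-regression HFO detector
#'
#' Maximum-likelihood logistic fit on the flattened (preprocessed) segment
#' vectors, via iteratively reweighted least squares ([stats::glm.fit()])
#' with a bounded iteration count. With more features than segments the fit
#' is rank-deficient; inestimable coefficients are set to zero for
#' prediction. On perfectly separable data the fit stops at the iteration
#' cap with a warning rather than diverging. `ridge > 0` switches to a
#' ridge-penalized fit (glmnet) for stability.
#'
#' @param data A labelled segment dataset tibble.
#' @param ridge Ridge penalty lambda (0 = pure maximum likelihood).
#' @param maxit IRLS iteration cap.
#' @return An object of class `hfo_lr` with a `predict()` method.
#' @export
train_lr <- function(data, ridge = 0, maxit = 50) {
  validate_segments(data)
  X <- segment_matrix(data)
  y <- as.numeric(data$label == "HFO")
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  if (ridge > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      abort("ridge > 0 requires the glmnet package")
    }
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = ridge)
    beta <- c(as.numeric(fit$a0), as.numeric(fit$beta))
    converged <- TRUE
  } else {
    fit <- suppressWarnings(
      glm.fit(cbind(1, X), y, family = binomial(),
              control = list(maxit = maxit))
    )
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    converged <- fit$converged
    if (!converged) {
      warn("logistic fit stopped at the iteration cap (data may be separable)")
    }
  }
  structure(list(beta = beta, converged = converged, n_points = ncol(X),
                 n_train = nrow(X)),
            class = "hfo_lr")
}

#' @export
predict.hfo_lr <- function(object, new_data, threshold = 0.5, ...) {
  X <- if (is.matrix(new_data)) new_data else segment_matrix(new_data)
  if (nrow(X) == 0L) return(tibble(.prob = numeric(), .pred = character()))
  probs <- as.numeric(plogis(cbind(1, X) %*% object$beta))
  tibble(.prob = probs, .pred = ifelse(probs >= threshold, "HFO", "NC"))
}

# ---- stacked sparse autoencoder (SSAE) detector ---------------------------

#' SSAE detector configuration
#'
#' A 4-layer network: input, three sparse autoencoder hidden layers
#' (30 units each by default, sigmoid activations), and a logistic output
#' unit. Hidden layers are pre-trained greedily as autoencoders whose loss
#' adds an L2 weight penalty and a KL-divergence sparsity penalty pulling
#' the mean hidden activation toward `sparsity_proportion`; the stack is
#' then fine-tuned with cross-entropy. Fine-tuning stops early when the
#' validation loss is identical (within 1e-9) for `early_stop_patience`
#' consecutive epochs.
#'
#' @param hidden_sizes Hidden layer widths.
#' @param sparsity_proportion Target mean activation, from the 0.1-0.5 grid.
#' @param l2_weight L2 penalty weight, from the 0.1-0.5 grid.
#' @param sparsity_weight Weight of the KL sparsity penalty.
#' @param learning_rate RMSprop learning rate (default 0.01).
#' @param pretrain_epochs Epochs per autoencoder layer.
#' @param finetune_epochs Cap on supervised fine-tuning epochs.
#' @param early_stop_patience Equal-validation-loss epochs before stopping.
#' @param val_fraction Fraction held out for validation during fine-tuning.
#' @param batch_size Mini-batch size.
#' @param seed Optional integer seed.
#' @return An object of class `ssae_config`.
#' @export
ssae_config <- function(hidden_sizes = c(30, 30, 30),
                        sparsity_proportion = 0.1, l2_weight = 0.1,
                        sparsity_weight = 0.5, learning_rate = 0.01,
                        pretrain_epochs = 15, finetune_epochs = 30,
                        early_stop_patience = 3, val_fraction = 0.2,
                        batch_size = 32, seed = NULL) {
  if (!length(hidden_sizes)) abort("hidden_sizes must be non-empty")
  if (sparsity_proportion <= 0 || sparsity_proportion >= 1) {
    abort("sparsity_proportion must lie in (0, 1)")
  }
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 sparsity_proportion = sparsity_proportion,
                 l2_weight = l2_weight, sparsity_weight = sparsity_weight,
                 learning_rate = learning_rate,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size), seed = seed),
            class = "ssae_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' KL-divergence sparsity penalty
#'
#' `sum_j KL(rho || rho_hat_j)` between the target activation proportion and
#' the observed mean activations; zero exactly when every unit's mean
#' activation equals the target.
#'
#' @param rho Target proportion in (0, 1).
#' @param rho_hat Vector of mean hidden activations.
#' @return Non-negative scalar.
#' @export
kl_sparsity <- function(rho, rho_hat) {
  rho_hat <- pmin(pmax(rho_hat, 1e-6), 1 - 1e-6)
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

# Train one sparse autoencoder layer (sigmoid encoder, linear decoder,
# squared-error reconstruction + L2 + KL sparsity) with RMSprop.
# Returns encoder weights and the per-epoch reconstruction loss.
train_sparse_ae <- function(X, hidden, cfg) {
  din <- ncol(X)
  W <- glorot(din, hidden)
  b <- numeric(hidden)
  Wd <- glorot(hidden, din)
  bd <- numeric(din)
  theta <- c(W, b, Wd, bd)
  v <- numeric(length(theta))
  unpack <- function(th) {
    list(W = matrix(th[seq_len(din * hidden)], din, hidden),
         b = th[din * hidden + seq_len(hidden)],
         Wd = matrix(th[din * hidden + hidden + seq_len(hidden * din)],
                     hidden, din),
         bd = th[din * hidden + hidden + hidden * din + seq_len(din)])
  }
  history <- numeric(cfg$pretrain_epochs)
  for (ep in seq_len(cfg$pretrain_epochs)) {
    ord <- sample.int(nrow(X))
    losses <- c()
    for (start in seq(1, nrow(X), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, nrow(X))]
      Xb <- X[idx, , drop = FALSE]
      B <- nrow(Xb)
      pr <- unpack(theta)
      H <- sigmoid(sweep(Xb %*% pr$W, 2, pr$b, "+"))
      R <- sweep(H %*% pr$Wd, 2, pr$bd, "+")
      rho_hat <- colMeans(H)
      recon <- mean(rowSums((R - Xb)^2)) / 2
      loss <- recon +
        cfg$l2_weight / 2 * (sum(pr$W^2) + sum(pr$Wd^2)) +
        cfg$sparsity_weight * kl_sparsity(cfg$sparsity_proportion, rho_hat)
      dR <- (R - Xb) / B
      dWd <- t(H) %*% dR + cfg$l2_weight * pr$Wd
      dbd <- colSums(dR)
      rh <- pmin(pmax(rho_hat, 1e-6), 1 - 1e-6)
      dKL <- cfg$sparsity_weight *
        (-cfg$sparsity_proportion / rh +
           (1 - cfg$sparsity_proportion) / (1 - rh)) / B
      dH <- dR %*% t(pr$Wd) +
        matrix(dKL, B, hidden, byrow = TRUE)
      dZ <- dH * H * (1 - H)
      dW <- t(Xb) %*% dZ + cfg$l2_weight * pr$W
      db <- colSums(dZ)
      step <- rmsprop_step(theta, c(dW, db, dWd, dbd), v,
                           lr = cfg$learning_rate)
      theta <- step$theta
      v <- step$v
      losses <- c(losses, recon)
    }
    history[ep] <- mean(losses)
  }
  pr <- unpack(theta)
  list(W = pr$W, b = pr$b, history = history)
}

#' Train the SSAE (SMO) detector
#'
#' Greedy layer-wise sparse-autoencoder pre-training followed by supervised
#' fine-tuning of the full stack with a logistic output unit, as configured
#' by [ssae_config()].
#'
#' @param data A labelled segment dataset tibble.
#' @param cfg An [ssae_config()].
#' @return An object of class `hfo_ssae` with a `predict()` method; carries
#'   the per-layer pre-training reconstruction histories and the
#'   fine-tuning validation-loss trace.
#' @export
train_ssae <- function(data, cfg = ssae_config()) {
  validate_segments(data)
  X <- segment_matrix(data)
  y <- as.numeric(data$label == "HFO")
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  run <- function() {
    n <- nrow(X)
    n_val <- max(1L, round(cfg$val_fraction * n))
    if (n - n_val < 2L) abort("too few samples for a validation split")
    val_idx <- sample.int(n, n_val)
    if (length(unique(y[-val_idx])) < 2) {
      abort("degenerate validation split: one class missing from training")
    }
    Xtr <- X[-val_idx, , drop = FALSE]
    ytr <- y[-val_idx]
    Xval <- X[val_idx, , drop = FALSE]
    yval <- y[val_idx]

    enc <- list()
    pre_hist <- list()
    inp <- Xtr
    for (hsz in cfg$hidden_sizes) {
      ae <- train_sparse_ae(inp, hsz, cfg)
      enc[[length(enc) + 1]] <- list(W = ae$W, b = ae$b)
      pre_hist[[length(pre_hist) + 1]] <- ae$history
      inp <- sigmoid(sweep(inp %*% ae$W, 2, ae$b, "+"))
    }
    w_out <- glorot(ncol(inp), 1)
    b_out <- 0

    pack <- function() {
      c(unlist(lapply(enc, function(e) c(e$W, e$b))), w_out, b_out)
    }
    unpack <- function(th) {
      pos <- 0L
      dims <- c(ncol(X), cfg$hidden_sizes)
      e <- vector("list", length(cfg$hidden_sizes))
      for (j in seq_along(cfg$hidden_sizes)) {
        nw <- dims[j] * dims[j + 1]
        e[[j]] <- list(W = matrix(th[pos + seq_len(nw)], dims[j], dims[j + 1]),
                       b = th[pos + nw + seq_len(dims[j + 1])])
        pos <- pos + nw + dims[j + 1]
      }
      last <- utils::tail(cfg$hidden_sizes, 1)
      list(enc = e, w_out = matrix(th[pos + seq_len(last)], last, 1),
           b_out = th[pos + last + 1])
    }
    fwd <- function(pr, Xb) {
      Hs <- list(Xb)
      for (e in pr$enc) {
        Hs[[length(Hs) + 1]] <-
          sigmoid(sweep(Hs[[length(Hs)]] %*% e$W, 2, e$b, "+"))
      }
      p <- as.numeric(sigmoid(Hs[[length(Hs)]] %*% pr$w_out + pr$b_out))
      list(p = p, Hs = Hs)
    }
    net_loss <- function(pr, Xb, yb) {
      cross_entropy_loss(yb, fwd(pr, Xb)$p) +
        cfg$l2_weight / 2 *
          (sum(unlist(lapply(pr$enc, function(e) sum(e$W^2)))) +
             sum(pr$w_out^2))
    }

    theta <- pack()
    v <- numeric(length(theta))
    val_hist <- c()
    equal_run <- 0L
    for (ep in seq_len(cfg$finetune_epochs)) {
      ord <- sample.int(nrow(Xtr))
      for (start in seq(1, nrow(Xtr), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, nrow(Xtr))]
        Xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        B <- nrow(Xb)
        pr <- unpack(theta)
        f <- fwd(pr, Xb)
        dlog <- matrix((f$p - yb) / B, ncol = 1)
        gw_out <- t(f$Hs[[length(f$Hs)]]) %*% dlog +
          cfg$l2_weight * pr$w_out
        gb_out <- sum(dlog)
        dH <- dlog %*% t(pr$w_out)
        genc <- vector("list", length(pr$enc))
        for (j in rev(seq_along(pr$enc))) {
          Hj <- f$Hs[[j + 1]]
          dZ <- dH * Hj * (1 - Hj)
          genc[[j]] <- list(W = t(f$Hs[[j]]) %*% dZ +
                              cfg$l2_weight * pr$enc[[j]]$W,
                            b = colSums(dZ))
          dH <- dZ %*% t(pr$enc[[j]]$W)
        }
        grad <- c(unlist(lapply(genc, function(g) c(g$W, g$b))),
                  gw_out, gb_out)
        step <- rmsprop_step(theta, grad, v, lr = cfg$learning_rate)
        theta <- step$theta
        v <- step$v
      }
      vl <- net_loss(unpack(theta), Xval, yval)
      if (length(val_hist) &&
          abs(vl - utils::tail(val_hist, 1)) < 1e-9) {
        equal_run <- equal_run + 1L
      } else {
        equal_run <- 0L
      }
      val_hist <- c(val_hist, vl)
      if (equal_run >= cfg$early_stop_patience) break
    }
    pr <- unpack(theta)
    list(enc = pr$enc, w_out = pr$w_out, b_out = pr$b_out,
         pretrain_history = pre_hist, val_history = val_hist)
  }
  fit <- with_seed_or_current(cfg$seed, run())
  structure(c(fit, list(config = cfg, n_points = ncol(X))),
            class = "hfo_ssae")
}

#' @export
predict.hfo_ssae <- function(object, new_data, threshold = 0.5, ...) {
  X <- if (is.matrix(new_data)) new_data else segment_matrix(new_data)
  if (nrow(X) == 0L) return(tibble(.prob = numeric(), .pred = character()))
  H <- X
  for (e in object$enc) H <- sigmoid(sweep(H %*% e$W, 2, e$b, "+"))
  probs <- as.numeric(sigmoid(H %*% object$w_out + object$b_out))
  tibble(.prob = probs, .pred = ifelse(probs >= threshold, "HFO", "NC"))
}

#' Select SSAE hyperparameters from the standard grids
#'
#' Grid search over sparsity proportion and L2 weight (each from
#' 0.1, ..., 0.5 by default), scored by validation accuracy on a stratified
#' hold-out split.
#'
#' @param data A labelled segment dataset tibble.
#' @param sparsity_grid,l2_grid Candidate values.
#' @param cfg Base [ssae_config()] whose other fields are reused.
#' @param seed Integer seed for the split and each fit.
#' @return A list with the winning `config` and the full `results` tibble.
#' @export
select_ssae_hyperparams <- function(data,
                                    sparsity_grid = seq(0.1, 0.5, by = 0.1),
                                    l2_grid = seq(0.1, 0.5, by = 0.1),
                                    cfg = ssae_config(), seed = NULL) {
  validate_segments(data)
  idx <- with_seed_or_current(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$label), function(ii) {
      sample(ii, max(1L, round(0.2 * length(ii))))
    }), use.names = FALSE)
  })
  train <- data[-idx, ]
  val <- data[idx, ]
  grid <- expand.grid(sparsity = sparsity_grid, l2 = l2_grid)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$sparsity_proportion <- grid$sparsity[i]
    cfg_i$l2_weight <- grid$l2[i]
    cfg_i$seed <- seed
    fit <- train_ssae(train, cfg_i)
    mean(predict(fit, val)$.pred == val$label)
  }, numeric(1))
  best <- which.max(acc)
  cfg$sparsity_proportion <- grid$sparsity[best]
  cfg$l2_weight <- grid$l2[best]
  list(config = cfg,
       results = tibble(sparsity = grid$sparsity, l2 = grid$l2,
                        val_accuracy = acc))
}
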