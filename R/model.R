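#' TransHFO architecture configuration
#'
#' Hyperparameters of the attention classifier. A segment of `T` samples is
#' cut into `T / frame_width` non-overlapping frames (tokens) of
#' `frame_width` samples, linearly projected to `d_model` dimensions, passed
#' through a dropout layer and `n_layers` identical blocks, and classified
#' by a dense head (`dense_units`, ReLU activations, final unit sigmoid).
#' Each block wraps two sublayers - multi-head self-attention (or its dense
#' replacement for the ResDen variant) and a position-wise feed-forward
#' network - in `Norm(ReLU(sublayer(x) + x))`; `norm = "postnorm"` selects
#' the conventional `Norm(x + sublayer(x))` instead. Per head,
#' `d_k = d_v = d_model / n_heads`.
#'
#' @param n_layers Number of stacked blocks N (0 degenerates to the dense
#'   head alone).
#' @param n_heads Number of attention heads h; must divide `d_model`.
#' @param d_model Token embedding width d.
#' @param frame_width Samples per token; must divide the segment length.
#' @param dropout Dropout rate applied to the input frames during training.
#' @param dense_units Widths of the classification head; must end in 1.
#' @param ffn_width Width of the position-wise feed-forward sublayer.
#' @param scale `"sqrt_dk"` scales attention scores by 1/sqrt(d_k) (the
#'   standard form); `"linear_d"` scales by 1/d_k.
#' @param norm Residual wrapper: `"relu_residual"` (default,
#'   `Norm(ReLU(sub + x))`) or `"postnorm"` (`Norm(sub + x)`).
#' @param positional Add a sinusoidal positional encoding to the projected
#'   tokens (off by default: token order information is not required to
#'   detect a burst, and the faithful architecture has none).
#' @param pool `"flatten"` concatenates all token outputs before the head;
#'   `"mean"` averages them.
#' @param sublayer `"attention"` (TransHFO) or `"dense"` (ResDen).
#' @param dense_sublayer_units Width of the ResDen replacement sublayer.
#' @return An object of class `transhfo_config`.
#' @export
transhfo_config <- function(n_layers = 2, n_heads = 4, d_model = 64,
                            frame_width = 20, dropout = 0.1,
                            dense_units = c(128, 10, 1),
                            ffn_width = 4 * d_model,
                            scale = c("sqrt_dk", "linear_d"),
                            norm = c("relu_residual", "postnorm"),
                            positional = FALSE,
                            pool = c("flatten", "mean"),
                            sublayer = c("attention", "dense"),
                            dense_sublayer_units = 128) {
  scale <- match.arg(scale)
  norm <- match.arg(norm)
  pool <- match.arg(pool)
  sublayer <- match.arg(sublayer)
  if (n_layers < 0) abort("n_layers must be >= 0")
  if (d_model %% n_heads != 0) {
    abort("n_heads must divide d_model (d_k = d_v = d_model / n_heads)")
  }
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  if (tail(dense_units, 1) != 1) abort("dense_units must end in a single unit")
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_model = as.integer(d_model),
                 d_k = as.integer(d_model / n_heads),
                 frame_width = as.integer(frame_width), dropout = dropout,
                 dense_units = as.integer(dense_units),
                 ffn_width = as.integer(ffn_width), scale = scale,
                 norm = norm, positional = positional, pool = pool,
                 sublayer = sublayer,
                 dense_sublayer_units = as.integer(dense_sublayer_units)),
            class = "transhfo_config")
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 10).
#' @param learning_rate RMSprop learning rate (default 1e-3).
#' @param seed Optional integer seed; fixes initialization, shuffling and
#'   dropout, making training bit-reproducible.
#' @param optimizer Only `"rmsprop"` is provided.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, epochs = 10, learning_rate = 1e-3,
                         seed = NULL, optimizer = "rmsprop") {
  if (batch_size < 1) abort("batch_size must be >= 1")
  if (epochs < 1) abort("epochs must be >= 1")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  optimizer <- match.arg(optimizer, "rmsprop")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = seed, optimizer = optimizer),
            class = "train_config")
}

#' Cut a segment into token frames
#'
#' Row i of the result holds samples `[(i-1) * frame_width + 1, i * frame_width]`,
#' so flattening the rows recovers the original segment. The learned linear
#' projection to `d_model` happens inside the model.
#'
#' @param x Numeric waveform whose length is a multiple of `frame_width`.
#' @param frame_width Samples per token.
#' @return A `length(x)/frame_width` x `frame_width` matrix.
#' @export
frame_tokens <- function(x, frame_width) {
  if (length(x) %% frame_width != 0) {
    divs <- which(length(x) %% seq_len(length(x)) == 0)
    abort(paste0("frame_width must divide the segment length ", length(x),
                 "; valid widths include: ",
                 paste(head(divs, 12), collapse = ", "), ", ..."))
  }
  matrix(x, ncol = frame_width, byrow = TRUE)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V` with the softmax applied row-wise, so each
#' output row is a convex combination of the rows of `V`. `scale =
#' "linear_d"` divides scores by `d_k` instead of its square root.
#'
#' @param Q,K Query and key matrices, n x d_k.
#' @param V Value matrix, n x d_v.
#' @param scale Score scaling variant.
#' @return The n x d_v output matrix, with the attention weight matrix
#'   attached as attribute `"weights"`.
#' @examples
#' scaled_attention(diag(2), diag(2), diag(2))
#' @export
scaled_attention <- function(Q, K, V, scale = c("sqrt_dk", "linear_d")) {
  scale <- match.arg(scale)
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V) || nrow(Q) != nrow(K)) {
    abort("Q, K, V must be conformable: Q,K n x d_k and V n x d_v")
  }
  scl <- if (scale == "sqrt_dk") 1 / sqrt(ncol(K)) else 1 / ncol(K)
  A <- softmax_rows(Q %*% t(K) * scl)
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

#' Multi-head self-attention
#'
#' Computes h heads of [scaled_attention()] on learned projections of the
#' same token matrix (`Q = K = V = X`), concatenates them and reprojects:
#' `Concat(head_1, ..., head_h) W_O`. The per-head projections are stored as
#' column blocks of `Wq`, `Wk`, `Wv` (head j uses columns
#' `((j-1) d_k + 1):(j d_k)`).
#'
#' @param X Token matrix, n x d.
#' @param Wq,Wk,Wv Projection matrices, d x (h d_k).
#' @param Wo Output projection, (h d_v) x d.
#' @param n_heads Number of heads h; must divide `ncol(Wq)`.
#' @param scale Score scaling variant, see [scaled_attention()].
#' @return The n x d output matrix.
#' @export
multi_head_attention <- function(X, Wq, Wk, Wv, Wo, n_heads,
                                 scale = c("sqrt_dk", "linear_d")) {
  scale <- match.arg(scale)
  if (ncol(Wq) %% n_heads != 0) abort("n_heads must divide the projection width")
  dk <- ncol(Wq) / n_heads
  Qa <- X %*% Wq
  Ka <- X %*% Wk
  Va <- X %*% Wv
  H <- matrix(0, nrow(X), ncol(Wv))
  for (j in seq_len(n_heads)) {
    cols <- ((j - 1) * dk + 1):(j * dk)
    hj <- scaled_attention(Qa[, cols, drop = FALSE], Ka[, cols, drop = FALSE],
                           Va[, cols, drop = FALSE], scale = scale)
    H[, cols] <- hj
  }
  H %*% Wo
}

#' Row-wise layer normalization
#'
#' Standardizes every row to zero mean and unit variance (population
#' variance, stabilized by `eps`) and applies a learned per-feature affine
#' transform.
#'
#' @param X Numeric matrix.
#' @param gain,bias Per-column affine parameters (default identity).
#' @param eps Variance floor.
#' @return Matrix of the same shape.
#' @export
layer_norm <- function(X, gain = rep(1, ncol(X)), bias = rep(0, ncol(X)),
                       eps = 1e-5) {
  layer_norm_fwd(X, gain, bias, eps)$out
}

#' Residual sublayer wrapper
#'
#' The block wrapper applied around each sublayer:
#' `Norm(ReLU(sublayer_out + X))` in the default (as-specified) form, or the
#' conventional `Norm(sublayer_out + X)` with `norm = "postnorm"`. Passing a
#' zero `sublayer_out` isolates the residual path, giving `Norm(ReLU(X))`.
#'
#' @param X Token matrix, n x d.
#' @param sublayer_out Sublayer output, n x d (or a scalar 0).
#' @param gain,bias Layer-norm affine parameters.
#' @param norm Wrapper variant.
#' @return Matrix of the same shape as `X`.
#' @export
residual_norm <- function(X, sublayer_out, gain = rep(1, ncol(X)),
                          bias = rep(0, ncol(X)),
                          norm = c("relu_residual", "postnorm")) {
  norm <- match.arg(norm)
  U <- X + sublayer_out
  if (norm == "relu_residual") U <- pmax(U, 0)
  layer_norm(U, gain, bias)
}

# ---- internal batched forward / backward ---------------------------------

attention_sublayer_fwd <- function(X, lp, config, B, n) {
  h <- config$n_heads
  dk <- config$d_k
  scl <- if (config$scale == "sqrt_dk") 1 / sqrt(dk) else 1 / dk
  Qa <- X %*% lp$Wq
  Ka <- X %*% lp$Wk
  Va <- X %*% lp$Wv
  H <- matrix(0, nrow(X), ncol(Va))
  A_list <- vector("list", B * h)
  for (b in seq_len(B)) {
    idx <- ((b - 1) * n + 1):(b * n)
    for (j in seq_len(h)) {
      cols <- ((j - 1) * dk + 1):(j * dk)
      S <- Qa[idx, cols, drop = FALSE] %*%
        t(Ka[idx, cols, drop = FALSE]) * scl
      A <- softmax_rows(S)
      H[idx, cols] <- A %*% Va[idx, cols, drop = FALSE]
      A_list[[(b - 1) * h + j]] <- A
    }
  }
  list(out = H %*% lp$Wo,
       cache = list(Qa = Qa, Ka = Ka, Va = Va, H = H, A_list = A_list,
                    scl = scl))
}

attention_sublayer_bwd <- function(dout, X, lp, cache, config, B, n) {
  h <- config$n_heads
  dk <- config$d_k
  dWo <- t(cache$H) %*% dout
  dH <- dout %*% t(lp$Wo)
  dQa <- matrix(0, nrow(X), ncol(lp$Wq))
  dKa <- dQa
  dVa <- dQa
  for (b in seq_len(B)) {
    idx <- ((b - 1) * n + 1):(b * n)
    for (j in seq_len(h)) {
      cols <- ((j - 1) * dk + 1):(j * dk)
      A <- cache$A_list[[(b - 1) * h + j]]
      dHj <- dH[idx, cols, drop = FALSE]
      dA <- dHj %*% t(cache$Va[idx, cols, drop = FALSE])
      dVa[idx, cols] <- t(A) %*% dHj
      dS <- softmax_rows_grad(A, dA)
      dQa[idx, cols] <- dS %*% cache$Ka[idx, cols, drop = FALSE] * cache$scl
      dKa[idx, cols] <- t(dS) %*% cache$Qa[idx, cols, drop = FALSE] * cache$scl
    }
  }
  dX <- dQa %*% t(lp$Wq) + dKa %*% t(lp$Wk) + dVa %*% t(lp$Wv)
  list(dX = dX,
       grads = list(Wq = t(X) %*% dQa, Wk = t(X) %*% dKa,
                    Wv = t(X) %*% dVa, Wo = dWo))
}

dense_sublayer_fwd <- function(X, lp) {
  H1 <- pmax(sweep(X %*% lp$Wr1, 2, lp$br1, "+"), 0)
  list(out = sweep(H1 %*% lp$Wr2, 2, lp$br2, "+"), cache = list(H1 = H1))
}

dense_sublayer_bwd <- function(dout, X, lp, cache) {
  dH1 <- (dout %*% t(lp$Wr2)) * (cache$H1 > 0)
  list(dX = dH1 %*% t(lp$Wr1),
       grads = list(Wr1 = t(X) %*% dH1, br1 = colSums(dH1),
                    Wr2 = t(cache$H1) %*% dout, br2 = colSums(dout)))
}

ffn_fwd <- function(Z, lp) {
  Hf <- pmax(sweep(Z %*% lp$W1, 2, lp$b1, "+"), 0)
  list(out = sweep(Hf %*% lp$W2, 2, lp$b2, "+"), cache = list(Hf = Hf))
}

ffn_bwd <- function(dout, Z, lp, cache) {
  dHf <- (dout %*% t(lp$W2)) * (cache$Hf > 0)
  list(dZ = dHf %*% t(lp$W1),
       grads = list(W1 = t(Z) %*% dHf, b1 = colSums(dHf),
                    W2 = t(cache$Hf) %*% dout, b2 = colSums(dout)))
}

wrapper_fwd <- function(X, sub_out, gain, bias, norm) {
  U <- X + sub_out
  R <- if (norm == "relu_residual") pmax(U, 0) else U
  ln <- layer_norm_fwd(R, gain, bias)
  list(out = ln$out, U = U, ln = ln)
}

wrapper_bwd <- function(dout, wcache, gain, norm) {
  lb <- layer_norm_bwd(wcache$ln, gain, dout)
  dU <- if (norm == "relu_residual") lb$dX * (wcache$U > 0) else lb$dX
  list(dU = dU, dgain = lb$dgain, dbias = lb$dbias)
}

layer_fwd <- function(X, lp, config, B, n) {
  sub <- if (config$sublayer == "attention") {
    attention_sublayer_fwd(X, lp, config, B, n)
  } else {
    dense_sublayer_fwd(X, lp)
  }
  w1 <- wrapper_fwd(X, sub$out, lp$g1, lp$be1, config$norm)
  ff <- ffn_fwd(w1$out, lp)
  w2 <- wrapper_fwd(w1$out, ff$out, lp$g2, lp$be2, config$norm)
  list(out = w2$out,
       cache = list(X = X, sub = sub$cache, w1 = w1, Z1 = w1$out,
                    ff = ff$cache, w2 = w2))
}

layer_bwd <- function(dZ2, cache, lp, config, B, n) {
  wb2 <- wrapper_bwd(dZ2, cache$w2, lp$g2, config$norm)
  fb <- ffn_bwd(wb2$dU, cache$Z1, lp, cache$ff)
  dZ1 <- wb2$dU + fb$dZ
  wb1 <- wrapper_bwd(dZ1, cache$w1, lp$g1, config$norm)
  sb <- if (config$sublayer == "attention") {
    attention_sublayer_bwd(wb1$dU, cache$X, lp, cache$sub, config, B, n)
  } else {
    dense_sublayer_bwd(wb1$dU, cache$X, lp, cache$sub)
  }
  grads <- c(sb$grads,
             list(g1 = wb1$dgain, be1 = wb1$dbias),
             fb$grads,
             list(g2 = wb2$dgain, be2 = wb2$dbias))
  list(dX = wb1$dU + sb$dX, grads = grads)
}

head_fwd <- function(S, head) {
  m <- length(head)
  Hs <- vector("list", m + 1)
  Hs[[1]] <- S
  for (j in seq_len(m)) {
    Z <- sweep(Hs[[j]] %*% head[[j]]$W, 2, head[[j]]$b, "+")
    Hs[[j + 1]] <- if (j < m) pmax(Z, 0) else Z
  }
  logit <- Hs[[m + 1]]
  list(prob = plogis(as.numeric(logit)), logit = logit, Hs = Hs)
}

head_bwd <- function(dlogit, cache, head) {
  m <- length(head)
  grads <- vector("list", m)
  dH <- dlogit
  for (j in rev(seq_len(m))) {
    if (j < m) dH <- dH * (cache$Hs[[j + 1]] > 0)
    grads[[j]] <- list(W = t(cache$Hs[[j]]) %*% dH, b = colSums(dH))
    dH <- dH %*% t(head[[j]]$W)
  }
  list(dS = dH, grads = grads)
}

init_transhfo_params <- function(config, n_points) {
  p <- config$frame_width
  d <- config$d_model
  n <- n_points %/% p
  u <- config$dense_sublayer_units
  f <- config$ffn_width
  layers <- lapply(seq_len(config$n_layers), function(l) {
    sub <- if (config$sublayer == "attention") {
      list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
           Wo = glorot(d, d))
    } else {
      list(Wr1 = glorot(d, u), br1 = numeric(u), Wr2 = glorot(u, d),
           br2 = numeric(d))
    }
    c(sub, list(g1 = rep(1, d), be1 = numeric(d),
                W1 = glorot(d, f), b1 = numeric(f),
                W2 = glorot(f, d), b2 = numeric(d),
                g2 = rep(1, d), be2 = numeric(d)))
  })
  in_dim <- if (config$pool == "flatten") n * d else d
  dims <- c(in_dim, config$dense_units)
  head <- lapply(seq_len(length(dims) - 1), function(j) {
    list(W = glorot(dims[j], dims[j + 1]), b = numeric(dims[j + 1]))
  })
  list(W_in = glorot(p, d), b_in = numeric(d), layers = layers, head = head)
}

model_fwd <- function(params, config, Xmat, training = FALSE) {
  B <- nrow(Xmat)
  p <- config$frame_width
  n <- ncol(Xmat) %/% p
  d <- config$d_model
  Fr <- matrix(as.vector(t(Xmat)), ncol = p, byrow = TRUE)
  if (training && config$dropout > 0) {
    mask <- matrix((runif(length(Fr)) >= config$dropout) /
                     (1 - config$dropout), nrow(Fr), ncol(Fr))
    Fr <- Fr * mask
  }
  X <- sweep(Fr %*% params$W_in, 2, params$b_in, "+")
  if (config$positional) {
    X <- X + positional_encoding(n, d)[rep(seq_len(n), B), , drop = FALSE]
  }
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lf <- layer_fwd(X, params$layers[[l]], config, B, n)
    layer_caches[[l]] <- lf$cache
    X <- lf$out
  }
  if (config$pool == "flatten") {
    tZ <- t(X)
    dim(tZ) <- c(d * n, B)
    S <- t(tZ)
  } else {
    S <- rowsum(X, rep(seq_len(B), each = n)) / n
  }
  hf <- head_fwd(S, params$head)
  list(prob = hf$prob, Fr = Fr, layer_caches = layer_caches, head = hf,
       B = B, n = n, d = d)
}

model_loss_grad <- function(params, config, Xmat, y, training = TRUE) {
  fw <- model_fwd(params, config, Xmat, training = training)
  B <- fw$B
  n <- fw$n
  d <- fw$d
  loss <- cross_entropy_loss(y, fw$prob)
  dlogit <- matrix((fw$prob - y) / B, ncol = 1)
  hb <- head_bwd(dlogit, fw$head, params$head)
  if (config$pool == "flatten") {
    tmp <- t(hb$dS)
    dim(tmp) <- c(d, n * B)
    dX <- t(tmp)
  } else {
    dX <- hb$dS[rep(seq_len(B), each = n), , drop = FALSE] / n
  }
  layer_grads <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    lb <- layer_bwd(dX, fw$layer_caches[[l]], params$layers[[l]], config, B, n)
    layer_grads[[l]] <- lb$grads
    dX <- lb$dX
  }
  grads <- list(W_in = t(fw$Fr) %*% dX, b_in = colSums(dX),
                layers = layer_grads, head = hb$grads)
  list(loss = loss, grads = grads, prob = fw$prob)
}

# ---- public training / prediction ----------------------------------------

#' Binary cross-entropy loss
#'
#' Mean over the batch of `-(y log p + (1 - y) log(1 - p))`, with
#' probabilities clipped to `[eps, 1 - eps]` so the loss stays finite at the
#' boundaries.
#'
#' @param y Binary labels (0/1 numeric, or `"HFO"`/`"NC"` characters with
#'   HFO as the positive class).
#' @param p Predicted probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return A non-negative scalar.
#' @examples
#' cross_entropy_loss(1, 0.5)  # log(2)
#' @export
cross_entropy_loss <- function(y, p, eps = 1e-7) {
  if (is.character(y) || is.factor(y)) y <- as.numeric(as.character(y) == "HFO")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' One block of the attention classifier
#'
#' Applies a full block - attention (or dense) sublayer and feed-forward
#' sublayer, each in the residual wrapper - to one token matrix. Stacking N
#' blocks is exactly N sequential applications of this function.
#'
#' @param X Token matrix, n x d.
#' @param layer_params One element of a trained model's `params$layers`.
#' @param config The model's [transhfo_config()].
#' @return The transformed n x d token matrix.
#' @export
transformer_layer <- function(X, layer_params, config) {
  layer_fwd(X, layer_params, config, B = 1L, n = nrow(X))$out
}

#' Train the attention classifier
#'
#' Trains TransHFO (or ResDen, via `sublayer = "dense"` in the config) with
#' RMSprop on shuffled mini-batches of labelled segments for exactly
#' `tconfig$epochs` epochs. Fully reproducible given `tconfig$seed`:
#' initialization, batch order and dropout all derive from it.
#'
#' @param data A labelled segment dataset tibble with both classes present
#'   (waveforms are used as-is; run [preprocess_segments()] first).
#' @param config A [transhfo_config()].
#' @param tconfig A [train_config()].
#' @return An object of class `transhfo_model` with elements `params`,
#'   `config`, `tconfig`, `n_points` and `history` (one mean loss per
#'   epoch).
#' @examples
#' ds <- simulate_dataset(8, 8, n_points = 200, freq_range = c(150, 300),
#'                        duration_range = c(0.04, 0.06), seed = 1) |>
#'   preprocess_segments()
#' fit <- train_transhfo(ds,
#'   transhfo_config(n_layers = 1, n_heads = 2, d_model = 8, frame_width = 20,
#'                   dense_units = c(8, 1), ffn_width = 16),
#'   train_config(epochs = 2, seed = 1))
#' fit$history
#' @export
train_transhfo <- function(data, config = transhfo_config(),
                           tconfig = train_config()) {
  validate_segments(data)
  if (any(data$label == "UNLABELED")) {
    abort("training data must be fully labelled")
  }
  y <- as.numeric(data$label == "HFO")
  if (length(unique(data$label)) < 2) {
    abort("training data must contain both classes")
  }
  Xmat <- segment_matrix(data)
  if (ncol(Xmat) %% config$frame_width != 0) {
    abort(paste0("frame_width (", config$frame_width,
                 ") must divide the segment length (", ncol(Xmat), ")"))
  }
  n_obs <- nrow(Xmat)
  run <- function() {
    params <- init_transhfo_params(config, ncol(Xmat))
    skel <- params
    theta <- flatten_params(params)
    v <- numeric(length(theta))
    history <- numeric(tconfig$epochs)
    for (ep in seq_len(tconfig$epochs)) {
      ord <- sample.int(n_obs)
      batch_losses <- c()
      for (start in seq(1, n_obs, by = tconfig$batch_size)) {
        idx <- ord[start:min(start + tconfig$batch_size - 1, n_obs)]
        lg <- model_loss_grad(unflatten_params(theta, skel), config,
                              Xmat[idx, , drop = FALSE], y[idx],
                              training = TRUE)
        step <- rmsprop_step(theta, flatten_params(lg$grads), v,
                             lr = tconfig$learning_rate)
        theta <- step$theta
        v <- step$v
        batch_losses <- c(batch_losses, lg$loss)
      }
      history[ep] <- mean(batch_losses)
    }
    list(params = unflatten_params(theta, skel), history = history)
  }
  fit <- with_seed_or_current(tconfig$seed, run())
  structure(list(params = fit$params, config = config, tconfig = tconfig,
                 n_points = ncol(Xmat), history = fit$history,
                 n_train = n_obs),
            class = "transhfo_model")
}

#' Predict HFO probabilities for segments
#'
#' Runs the trained classifier in inference mode (dropout off, so
#' predictions are deterministic). A segment is labelled `"HFO"` when its
#' probability is at least `threshold`.
#'
#' @param object A `transhfo_model`.
#' @param new_data A segment dataset tibble or a numeric matrix of segments.
#' @param threshold Decision threshold (default 0.5).
#' @param chunk_size Segments per forward pass.
#' @param ... Unused.
#' @return A tibble with columns `.prob` and `.pred` (`"HFO"`/`"NC"`), one
#'   row per input segment.
#' @export
predict.transhfo_model <- function(object, new_data, threshold = 0.5,
                                   chunk_size = 64, ...) {
  Xmat <- if (is.matrix(new_data)) new_data else segment_matrix(new_data)
  if (nrow(Xmat) == 0L) {
    return(tibble(.prob = numeric(), .pred = character()))
  }
  if (ncol(Xmat) != object$n_points) {
    abort(paste0("segments have ", ncol(Xmat), " samples; the model expects ",
                 object$n_points))
  }
  probs <- numeric(nrow(Xmat))
  for (start in seq(1, nrow(Xmat), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, nrow(Xmat))
    probs[idx] <- model_fwd(object$params, object$config,
                            Xmat[idx, , drop = FALSE],
                            training = FALSE)$prob
  }
  tibble(.prob = probs, .pred = ifelse(probs >= threshold, "HFO", "NC"))
}

#' @export
print.transhfo_model <- function(x, ...) {
  kind <- if (x$config$sublayer == "attention") "TransHFO" else "ResDen"
  cat(sprintf("<%s> N=%d layers, h=%d heads, d=%d, %d-sample segments; final loss %.4f\n",
              kind, x$config$n_layers, x$config$n_heads, x$config$d_model,
              x$n_points, tail(x$history, 1)))
  invisible(x)
}
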