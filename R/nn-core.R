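# Internal neural-network primitives: row-wise softmax and layer norm with
# their gradients, parameter (un)flattening, Glorot initialization, RMSprop.
# All operate on plain matrices; batches of segments are stacked row-wise
# (sample b occupies token rows ((b-1)n+1):(bn)).

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

# dL/dS given A = softmax_rows(S) and dL/dA.
softmax_rows_grad <- function(A, dA) {
  A * (dA - rowSums(dA * A))
}

# Row-wise layer normalization with learned per-feature gain/bias.
# Returns the output plus the cache needed for the backward pass.
layer_norm_fwd <- function(X, gain, bias, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2, gain, "*"), 2, bias, "+")
  list(out = out, xhat = xhat, inv = inv)
}

layer_norm_bwd <- function(cache, gain, dout) {
  dxhat <- sweep(dout, 2, gain, "*")
  xhat <- cache$xhat
  dX <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dgain = colSums(dout * xhat), dbias = colSums(dout))
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Flatten a nested parameter list to one numeric vector and back. The
# skeleton records the recursive structure and dimensions.
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  rebuild <- function(s) {
    if (is.list(s)) return(lapply(s, rebuild))
    n <- length(s)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  rebuild(skeleton)
}

# One RMSprop step on flat vectors: v <- rho v + (1-rho) g^2,
# theta <- theta - lr g / (sqrt(v) + eps). Returns updated theta and v.
rmsprop_step <- function(theta, grad, v, lr, rho = 0.9, eps = 1e-7) {
  v <- rho * v + (1 - rho) * grad^2
  list(theta = theta - lr * grad / (sqrt(v) + eps), v = v)
}

# Sinusoidal positional encoding (n tokens x d), optional in the model.
positional_encoding <- function(n, d) {
  pos <- seq_len(n) - 1
  i <- seq_len(d) - 1
  ang <- outer(pos, 1 / 10000^((i %/% 2) * 2 / d))
  pe <- matrix(0, n, d)
  even <- (i %% 2) == 0
  pe[, even] <- sin(ang[, even, drop = FALSE])
  pe[, !even] <- cos(ang[, !even, drop = FALSE])
  pe
}
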