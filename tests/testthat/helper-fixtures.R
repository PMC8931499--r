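# Shared fixtures, generated in code at test time.

# Small synthetic HFO/NC dataset (short segments keep unit tests fast).
tiny_dataset <- function(n_hfo = 10, n_nc = 10, n_points = 500,
                         amplitude = 3, seed = 1, fs = 2400) {
  simulate_dataset(n_hfo, n_nc, amplitude = amplitude,
                   freq_range = c(120, 300), duration_range = c(0.04, 0.08),
                   n_points = n_points, fs = fs, seed = seed)
}

# A reduced architecture for fast training in tests.
tiny_config <- function(n_layers = 1, n_heads = 2, d_model = 16,
                        frame_width = 20, dense_units = c(16, 4, 1),
                        ffn_width = 32, ...) {
  transhfo_config(n_layers = n_layers, n_heads = n_heads, d_model = d_model,
                  frame_width = frame_width, dense_units = dense_units,
                  ffn_width = ffn_width, ...)
}

# Trivially separable two-class Gaussian "segments" (mean-shifted), for
# exercising CV bookkeeping with a fast detector.
gauss_dataset <- function(n_per_class = 12, n_points = 16, shift = 2,
                          seed = 1) {
  withr::with_seed(seed, {
    hfo <- matrix(rnorm(n_per_class * n_points, mean = shift),
                  n_per_class, n_points)
    nc <- matrix(rnorm(n_per_class * n_points, mean = -shift),
                 n_per_class, n_points)
    segment_dataset(rbind(hfo, nc),
                    label = rep(c("HFO", "NC"), each = n_per_class),
                    fs = 2400)
  })
}

# Brute-force k-nearest-neighbour table by Euclidean distance (ties by
# lowest index), used as the independent oracle for ADASYN geometry.
brute_knn <- function(query, ref, k, exclude_self = FALSE) {
  t(sapply(seq_len(nrow(query)), function(i) {
    d <- apply(ref, 1, function(r) sqrt(sum((r - query[i, ])^2)))
    if (exclude_self) d[i] <- Inf
    order(d)[seq_len(k)]
  }))
}

# Periodogram frequencies and power for slope / peak oracles.
periodogram <- function(x, fs, pad = NULL) {
  n <- if (is.null(pad)) length(x) else pad
  X <- stats::fft(c(x, rep(0, n - length(x))))
  half <- seq_len(floor(n / 2))
  list(freq = (half - 1) * fs / n, power = Mod(X[half])^2)
}
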