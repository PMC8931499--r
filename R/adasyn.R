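#' Augmentation configuration
#'
#' Controls virtual sample generation. `factor` is the number of virtual
#' samples expressed as a multiple of the original dataset size, so
#' `factor = 5` on a 202-segment dataset yields 1010 virtual samples (and
#' `factor = 0` is a no-op). The three-bin scheme of [balanced_augment()]
#' deliberately constructs imbalance, so the classical ADASYN imbalance
#' threshold is bypassed there; it applies when [adasyn_generate()] is used
#' standalone through [adasyn_oversample()].
#'
#' @param factor Virtual-to-original size ratio (>= 0).
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @param bins Number of bins per class in the balanced-data scheme
#'   (default 3).
#' @param imbalance_threshold Maximum tolerated minority/majority ratio for
#'   standalone oversampling, in (0, 1].
#' @param seed Optional integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(factor = 1, k_neighbors = 5, bins = 3,
                           imbalance_threshold = 0.75, seed = NULL) {
  if (factor < 0) abort("factor must be non-negative")
  if (k_neighbors < 1) abort("k_neighbors must be >= 1")
  if (bins < 2) abort("bins must be >= 2")
  if (imbalance_threshold <= 0 || imbalance_threshold > 1) {
    abort("imbalance_threshold must lie in (0, 1]")
  }
  structure(list(factor = factor, k_neighbors = as.integer(k_neighbors),
                 bins = as.integer(bins),
                 imbalance_threshold = imbalance_threshold, seed = seed),
            class = "augment_config")
}

# k nearest neighbours of each row of `query` among rows of `ref` by
# Euclidean distance, excluding self-matches identified by index offset;
# ties broken by lowest index (stable order()).
knn_indices <- function(query, ref, k, self_offset = NA) {
  res <- vapply(seq_len(nrow(query)), function(i) {
    d <- sqrt(colSums((t(ref) - query[i, ])^2))
    if (!is.na(self_offset)) d[self_offset + i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k))
  # vapply collapses k = 1 to a plain vector; keep the n x k shape
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Generate ADASYN virtual samples
#'
#' Core adaptive synthetic oversampling. For each minority sample i, the k
#' nearest neighbours in the combined minority + majority set define a
#' hardness weight `r_i` = (majority neighbours)/k; weights are normalized
#' to sum to 1 and allocate the `n_synthetic` virtual samples (rounded
#' per-sample quotas are truncated or topped up, sampling parents
#' proportionally to the normalized weights, so the total is met exactly).
#' Each virtual sample is `x_i + lambda * (x_z - x_i)` with
#' `lambda ~ U[0, 1]` and `x_z` a uniform-random draw among x_i's k nearest
#' *minority* neighbours, i.e. a convex combination of two real minority
#' points. If no minority sample has a majority neighbour the allocation
#' falls back to uniform weights with a warning.
#'
#' @param minority Numeric matrix of minority-class samples (>= 2 rows).
#' @param majority Numeric matrix of majority-class samples (same width).
#' @param k_neighbors Number of neighbours; must be < `nrow(minority)`.
#' @param n_synthetic Number of virtual samples to generate.
#' @param seed Optional integer seed.
#' @return An object of class `virtual_sample_batch`: list with `samples`
#'   (matrix `n_synthetic` x width), `parent_indices` (tibble `i`,
#'   `neighbor`), `lambdas`, and the normalized weights `r_hat`.
#' @export
adasyn_generate <- function(minority, majority, k_neighbors = 5,
                            n_synthetic, seed = NULL) {
  minority <- as.matrix(minority)
  majority <- as.matrix(majority)
  nm <- nrow(minority)
  if (nm < 2L) abort("ADASYN needs at least 2 minority samples")
  if (k_neighbors >= nm) abort("k_neighbors must be smaller than the minority size")
  k <- as.integer(k_neighbors)

  combined <- rbind(minority, majority)
  nn_all <- knn_indices(minority, combined, k, self_offset = 0L)
  r <- rowSums(nn_all > nm) / k
  if (sum(r) == 0) {
    warn("no minority sample has a majority neighbour; using uniform weights")
    r_hat <- rep(1 / nm, nm)
  } else {
    r_hat <- r / sum(r)
  }
  nn_min <- knn_indices(minority, minority, k, self_offset = 0L)

  empty <- function() {
    structure(list(samples = matrix(numeric(0), 0, ncol(minority)),
                   parent_indices = tibble(i = integer(), neighbor = integer()),
                   lambdas = numeric(), r_hat = r_hat),
              class = "virtual_sample_batch")
  }
  if (n_synthetic == 0) return(empty())

  with_seed_or_current(seed, {
    g <- round(r_hat * n_synthetic)
    parents <- rep(seq_len(nm), g)
    if (length(parents) > n_synthetic) {
      parents <- parents[seq_len(n_synthetic)]
    } else if (length(parents) < n_synthetic) {
      extra <- sample(seq_len(nm), n_synthetic - length(parents),
                      replace = TRUE, prob = r_hat)
      parents <- c(parents, extra)
    }
    neigh_pick <- vapply(parents, function(i) nn_min[i, sample.int(k, 1L)],
                         integer(1))
    lambdas <- runif(n_synthetic)
    samples <- minority[parents, , drop = FALSE] +
      lambdas * (minority[neigh_pick, , drop = FALSE] -
                   minority[parents, , drop = FALSE])
    structure(list(samples = samples,
                   parent_indices = tibble(i = parents, neighbor = neigh_pick),
                   lambdas = lambdas, r_hat = r_hat),
              class = "virtual_sample_batch")
  })
}

#' Classical ADASYN oversampling of an imbalanced dataset
#'
#' Applies [adasyn_generate()] the textbook way: if the minority/majority
#' ratio is below `imbalance_threshold`, enough virtual minority samples are
#' generated to balance the classes.
#'
#' @param ds A labelled segment dataset tibble (both classes present).
#' @param cfg An [augment_config()].
#' @return The dataset with virtual minority segments appended
#'   (`source = "virtual"`), or unchanged if already balanced enough.
#' @export
adasyn_oversample <- function(ds, cfg = augment_config()) {
  validate_segments(ds)
  counts <- table(factor(ds$label, levels = c("NC", "HFO")))
  if (any(counts == 0)) abort("both classes must be present")
  minority_lab <- names(counts)[which.min(counts)]
  majority_lab <- setdiff(c("NC", "HFO"), minority_lab)[1]
  if (min(counts) / max(counts) >= cfg$imbalance_threshold) return(ds)
  n_syn <- max(counts) - min(counts)
  batch <- adasyn_generate(segment_matrix(ds[ds$label == minority_lab, ]),
                           segment_matrix(ds[ds$label == majority_lab, ]),
                           k_neighbors = min(cfg$k_neighbors,
                                             min(counts) - 1L),
                           n_synthetic = n_syn, seed = cfg$seed)
  bind_virtual(ds, batch$samples, minority_lab)
}

# Append a matrix of virtual samples to a dataset with provenance tags.
bind_virtual <- function(ds, samples, label) {
  if (nrow(samples) == 0L) return(ds)
  virt <- segment_dataset(samples, label = label, fs = ds$fs[1],
                          source = "virtual", channel_id = "virtual",
                          start_time = NA_real_)
  out <- dplyr::bind_rows(ds, virt)
  out$sample_id <- seq_len(nrow(out))
  out
}

#' Balanced-data virtual sample generation (three-bin scheme)
#'
#' ADASYN targets imbalanced data, but a gold-standard HFO/NC dataset is
#' balanced. This routine manufactures the imbalance: each class is split
#' into `bins` near-equal random bins, and one bin of the class being
#' synthesized is combined with the *whole* other class to form a temporary
#' imbalanced set on which [adasyn_generate()] runs. Bins rotate, and the
#' procedure repeats until `factor x nrow(dataset)` virtual samples exist,
#' split equally between the classes. Original samples pass through
#' bit-identically; virtual samples are tagged `source = "virtual"` and are
#' never used as gold standard.
#'
#' @param ds A labelled segment dataset tibble.
#' @param cfg An [augment_config()]; `factor = 0` returns the dataset
#'   unchanged.
#' @return The dataset with virtual segments appended.
#' @examples
#' ds <- simulate_dataset(6, 6, n_points = 200, freq_range = c(150, 300),
#'                        duration_range = c(0.04, 0.06), seed = 1)
#' aug <- balanced_augment(ds, augment_config(factor = 2, k_neighbors = 1,
#'                                            seed = 1))
#' class_counts(aug)
#' @export
balanced_augment <- function(ds, cfg = augment_config()) {
  validate_segments(ds)
  if (cfg$factor == 0) return(ds)
  labs <- c("HFO", "NC")
  counts <- vapply(labs, function(l) sum(ds$label == l), integer(1))
  if (any(counts < 2L)) {
    abort("each class needs at least 2 samples to generate virtual samples")
  }
  n_total <- nrow(ds)
  target <- round(cfg$factor * n_total)
  quota <- c(HFO = floor(target / 2), NC = target - floor(target / 2))

  seeds <- derive_seeds(cfg$seed, 2L * cfg$bins * 64L + 2L)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  virt <- list()
  for (lab in labs) {
    if (quota[[lab]] == 0) next
    other <- setdiff(labs, lab)
    own <- segment_matrix(ds[ds$label == lab, ])
    oth <- segment_matrix(ds[ds$label == other, ])
    # every bin must hold >= 2 samples for neighbour interpolation, so small
    # classes get fewer (possibly one) bins
    bins <- max(1L, min(cfg$bins, nrow(own) %/% 2L))
    bin_of <- with_seed_or_current(next_seed(), {
      sample(rep_len(seq_len(bins), nrow(own)))
    })
    made <- 0L
    chunks <- list()
    b <- 0L
    while (made < quota[[lab]]) {
      b <- b + 1L
      bin_idx <- which(bin_of == ((b - 1L) %% bins) + 1L)
      chunk <- min(ceiling(quota[[lab]] / bins), quota[[lab]] - made)
      k_eff <- min(cfg$k_neighbors, length(bin_idx) - 1L)
      batch <- adasyn_generate(own[bin_idx, , drop = FALSE], oth,
                               k_neighbors = k_eff, n_synthetic = chunk,
                               seed = next_seed())
      chunks[[b]] <- batch$samples
      made <- made + chunk
    }
    virt[[lab]] <- do.call(rbind, chunks)
  }
  out <- ds
  for (lab in labs) {
    if (!is.null(virt[[lab]])) out <- bind_virtual(out, virt[[lab]], lab)
  }
  out
}
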