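#' Confusion counts for binary HFO detection
#'
#' The positive class is `"HFO"`. Inputs may be `"HFO"`/`"NC"` character
#' vectors (or factors) or 0/1 numerics.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return A one-row tibble of class `confusion_counts` with columns `tp`,
#'   `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(y_true, y_pred) {
  to01 <- function(v) {
    if (is.character(v) || is.factor(v)) as.numeric(as.character(v) == "HFO")
    else as.numeric(v)
  }
  yt <- to01(y_true)
  yp <- to01(y_pred)
  if (length(yt) != length(yp)) abort("y_true and y_pred must have equal length")
  out <- tibble(tp = sum(yt == 1 & yp == 1), fp = sum(yt == 0 & yp == 1),
                tn = sum(yt == 0 & yp == 0), fn = sum(yt == 1 & yp == 0))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity and F-score:
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), F = 2 * precision * sensitivity /
#' (precision + sensitivity). A zero denominator yields 0 for that metric,
#' with a warning and `degenerate = TRUE`, rather than an error.
#'
#' @param counts A `confusion_counts` row (or anything with `tp`, `fp`,
#'   `tn`, `fn` fields).
#' @return A one-row tibble with the five metrics and a `degenerate` flag.
#' @examples
#' compute_metrics(confusion_counts(c(1, 1, 0), c(1, 1, 0)))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  tn <- counts$tn
  fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) abort("no evaluated segments")
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else {
      num / den
    }
  }
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  out <- tibble(
    accuracy = (tp + tn) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_div(tn, tn + fp),
    f_score = safe_div(2 * precision * sensitivity,
                       precision + sensitivity),
    degenerate = degenerate
  )
  if (degenerate) warn("a metric denominator was zero; reported as 0")
  out
}

# Stratified fold assignment: within each class, a seeded shuffle dealt
# round-robin over k folds.
stratified_folds <- function(labels, k, seed = NULL) {
  fold <- integer(length(labels))
  with_seed_or_current(seed, {
    for (lab in unique(labels)) {
      idx <- sample(which(labels == lab))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a detector
#'
#' Randomly partitions the dataset into k stratified folds. Per fold, the
#' training portion is (optionally) augmented with virtual samples via
#' [balanced_augment()], the detector is trained from scratch, and the
#' untouched test fold is scored - so virtual samples can never leak into
#' evaluation (asserted). The aggregate confusion matrix is the elementwise
#' sum over folds and every segment is tested exactly once.
#'
#' @param data A labelled segment dataset tibble; each class needs at least
#'   k members.
#' @param spec A `detector_spec`.
#' @param k Number of folds (default 5).
#' @param augment Optional [augment_config()] applied to each training fold
#'   (`NULL` or `factor = 0` disables augmentation).
#' @param seed Integer seed driving the partition and every per-fold train.
#' @return An object of class `cv_result`: list with `k`, `seed`, `folds`
#'   (per-fold counts tibble), `counts` (aggregate), `metrics`, and
#'   `assignments` (fold index per segment).
#' @export
kfold_cv <- function(data, spec, k = 5, augment = NULL, seed = NULL) {
  validate_segments(data)
  k <- as.integer(k)
  if (k < 2) abort("k must be >= 2")
  if (any(table(data$label) < k)) {
    abort("each class needs at least k segments")
  }
  if (any(data$source == "virtual")) {
    abort("virtual samples cannot serve as gold-standard evaluation data")
  }
  seeds <- derive_seeds(seed, 2L * k + 1L)
  fold <- stratified_folds(data$label, k, seed = seeds[1])
  fold_rows <- purrr::map(seq_len(k), function(i) {
    train <- data[fold != i, ]
    test <- data[fold == i, ]
    if (!is.null(augment) && augment$factor > 0) {
      aug <- augment
      aug$seed <- seeds[1 + k + i]
      train <- balanced_augment(train, aug)
    }
    model <- train_detector(spec, train, seed = seeds[1 + i])
    pred <- predict(model, test)
    cc <- confusion_counts(test$label, pred$.pred)
    dplyr::bind_cols(tibble(fold = i), cc,
                     tibble(test_virtual = sum(test$source == "virtual")))
  })
  folds <- dplyr::bind_rows(fold_rows)
  agg <- tibble(tp = sum(folds$tp), fp = sum(folds$fp),
                tn = sum(folds$tn), fn = sum(folds$fn))
  class(agg) <- c("confusion_counts", class(agg))
  structure(list(k = k, seed = seed, model = spec$label, folds = folds,
                 counts = agg, metrics = compute_metrics(agg),
                 assignments = fold,
                 leakage_ok = all(folds$test_virtual == 0)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold (seed %s)\n", x$model, x$k,
              format(x$seed)))
  print(x$metrics)
  invisible(x)
}

#' Depth-by-augmentation-factor performance sweep
#'
#' Runs one [kfold_cv()] per (depth N, augmentation factor) grid cell for a
#' network detector, with per-cell seeds derived from one base seed. The
#' leakage guard - no virtual sample in any test fold - is enforced inside
#' every cell and reported per cell.
#'
#' @param data A labelled segment dataset tibble.
#' @param spec A `transhfo_spec()` or `resden_spec()` whose `n_layers` is
#'   overridden cell by cell.
#' @param depths Integer vector of layer counts N.
#' @param factors Numeric vector of augmentation factors (0 = none; the
#'   full published grid is 0, 1, 5, 10, 20, 40).
#' @param k Folds per cell.
#' @param k_neighbors,bins Passed to [augment_config()].
#' @param seed Base integer seed.
#' @return A tibble of class `hfo_sweep`: one row per cell with the
#'   confusion counts, the five metrics and `leakage_ok`.
#' @export
depth_augmentation_sweep <- function(data, spec = transhfo_spec(),
                                     depths = c(1, 2, 4, 10, 20, 40),
                                     factors = c(0, 1, 5, 10, 20, 40),
                                     k = 5, k_neighbors = 5, bins = 3,
                                     seed = NULL) {
  if (!length(depths) || !length(factors)) abort("depths and factors must be non-empty")
  grid <- expand.grid(n_layers = depths, factor = factors)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$config$n_layers <- as.integer(grid$n_layers[i])
    aug <- if (grid$factor[i] > 0) {
      augment_config(factor = grid$factor[i], k_neighbors = k_neighbors,
                     bins = bins)
    } else {
      NULL
    }
    cv <- kfold_cv(data, sp, k = k, augment = aug, seed = seeds[i])
    dplyr::bind_cols(
      tibble(model = spec$label, n_layers = grid$n_layers[i],
             factor = grid$factor[i], k = k, seed = seeds[i]),
      tibble::as_tibble(cv$counts), cv$metrics,
      tibble(leakage_ok = cv$leakage_ok)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hfo_sweep", class(out))
  out
}

#' Write a sweep grid as tab-delimited text
#'
#' @param sweep An `hfo_sweep` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  readr::write_tsv(as_tibble(sweep), path)
  invisible(path)
}

#' Published reference metrics for HFO detector families
#'
#' A small bundled table of clinical-benchmark classification metrics
#' (accuracy, precision, sensitivity, specificity, F-score) reported in the
#' HFO-detection literature for logistic regression, the SMO stacked sparse
#' autoencoder and the ResDen network, with and without ADASYN
#' augmentation. Used to regression-test the F-score identity
#' `F = 2ps/(p + s)` against independently printed precision/sensitivity/F
#' triplets rounded to four decimals.
#'
#' @return A tibble with columns `model`, `augmented` and the five metrics.
#' @export
reference_detector_metrics <- function() {
  readr::read_csv(system.file("extdata", "reference_detector_metrics.csv",
                              package = "transhfo"),
                  show_col_types = FALSE, progress = FALSE)
}
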