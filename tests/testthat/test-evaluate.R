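test_that("confusion counts enumerate all four outcomes", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(as.integer(c(cc$tp, cc$fp, cc$tn, cc$fn)),
                   c(1L, 1L, 1L, 1L))
  perfect <- confusion_counts(c("HFO", "NC", "NC"), c("HFO", "NC", "NC"))
  expect_identical(as.integer(c(perfect$tp, perfect$fp, perfect$tn,
                                perfect$fn)), c(1L, 0L, 2L, 0L))
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
  mixed <- confusion_counts(c("HFO", "NC"), c(1, 0))
  expect_identical(as.integer(c(mixed$tp, mixed$tn)), c(1L, 1L))
})

test_that("metrics reproduce a worked confusion-matrix example", {
  m <- compute_metrics(tibble::tibble(tp = 10, fp = 1, tn = 11, fn = 4))
  expect_equal(round(m$accuracy, 4), 0.8077)
  expect_equal(round(m$precision, 4), 0.9091)
  expect_equal(round(m$sensitivity, 4), 0.7143)
  expect_equal(round(m$specificity, 4), 0.9167)
  expect_equal(round(m$f_score, 4), 0.8)
  expect_false(m$degenerate)
  p <- compute_metrics(tibble::tibble(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_true(all(unlist(p[1:5]) == 1))
})

test_that("metric identities hold on random confusion matrices", {
  for (s in 1:20) {
    cc <- withr::with_seed(s, tibble::tibble(
      tp = sample(1:50, 1), fp = sample(1:50, 1),
      tn = sample(1:50, 1), fn = sample(1:50, 1)))
    m <- compute_metrics(cc)
    pos <- cc$tp + cc$fn
    neg <- cc$tn + cc$fp
    expect_equal(m$accuracy,
                 (m$sensitivity * pos + m$specificity * neg) / (pos + neg),
                 tolerance = 1e-12)
    expect_equal(m$f_score,
                 2 * m$precision * m$sensitivity /
                   (m$precision + m$sensitivity),
                 tolerance = 1e-12)
    expect_true(all(unlist(m[1:5]) >= 0 & unlist(m[1:5]) <= 1))
  }
})

test_that("zero denominators degrade to 0 with a warning, not an error", {
  expect_warning(m <- compute_metrics(tibble::tibble(tp = 0, fp = 0,
                                                     tn = 5, fn = 5)),
                 "zero")
  expect_identical(m$precision, 0)
  expect_true(m$degenerate)
  expect_error(compute_metrics(tibble::tibble(tp = 0, fp = 0, tn = 0,
                                              fn = 0)), "no evaluated")
})

test_that("stratified folds partition each class as evenly as possible", {
  labels <- rep(c("HFO", "NC"), c(11, 9))
  fold <- stratified_folds(labels, k = 4, seed = 1)
  expect_length(fold, 20)
  expect_true(all(fold %in% 1:4))
  for (lab in c("HFO", "NC")) {
    per_fold <- table(factor(fold[labels == lab], levels = 1:4))
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_identical(stratified_folds(labels, 4, seed = 1), fold)
})

test_that("cross-validation tests every segment exactly once", {
  ds <- gauss_dataset(n_per_class = 12, n_points = 10, seed = 2)
  cv <- suppressWarnings(kfold_cv(ds, lr_spec(), k = 4, seed = 3))
  expect_identical(cv$k, 4L)
  expect_length(cv$assignments, nrow(ds))
  expect_identical(sum(cv$folds$tp + cv$folds$fp + cv$folds$tn +
                         cv$folds$fn), nrow(ds))
  expect_identical(as.integer(cv$counts$tp), sum(cv$folds$tp))
  expect_identical(as.integer(cv$counts$fn), sum(cv$folds$fn))
  expect_equal(cv$metrics,
               compute_metrics(cv$counts))
  expect_true(cv$leakage_ok)
  # separable data: the linear baseline should be near-perfect
  expect_gt(cv$metrics$accuracy, 0.9)
})

test_that("cross-validation is deterministic in its seed", {
  ds <- gauss_dataset(n_per_class = 10, n_points = 8, seed = 4)
  cv1 <- suppressWarnings(kfold_cv(ds, lr_spec(), k = 5, seed = 7))
  cv2 <- suppressWarnings(kfold_cv(ds, lr_spec(), k = 5, seed = 7))
  expect_identical(cv1$folds, cv2$folds)
  cv3 <- suppressWarnings(kfold_cv(ds, lr_spec(), k = 5, seed = 8))
  expect_false(identical(cv1$assignments, cv3$assignments))
})

test_that("virtual samples never reach a test fold", {
  ds <- gauss_dataset(n_per_class = 10, n_points = 8, seed = 5)
  cv <- suppressWarnings(
    kfold_cv(ds, lr_spec(), k = 5,
             augment = augment_config(factor = 1, k_neighbors = 3), seed = 1))
  expect_true(cv$leakage_ok)
  expect_true(all(cv$folds$test_virtual == 0))
  pre_augmented <- balanced_augment(ds, augment_config(factor = 1,
                                                       k_neighbors = 3,
                                                       seed = 1))
  expect_error(kfold_cv(pre_augmented, lr_spec(), k = 5, seed = 1),
               "virtual")
})

test_that("cross-validation validates its inputs", {
  ds <- gauss_dataset(n_per_class = 3, n_points = 8, seed = 6)
  expect_error(kfold_cv(ds, lr_spec(), k = 5, seed = 1), "at least k")
  expect_error(kfold_cv(ds, lr_spec(), k = 1, seed = 1), ">= 2")
})

test_that("the sweep covers the full depth-by-factor grid", {
  ds <- tiny_dataset(8, 8, n_points = 200, seed = 7) |> preprocess_segments()
  spec <- transhfo_spec(tiny_config(frame_width = 10, d_model = 8,
                                    n_heads = 2, ffn_width = 16,
                                    dense_units = c(4, 1)),
                        train_config(epochs = 1))
  sw <- depth_augmentation_sweep(ds, spec, depths = c(1, 2),
                                 factors = c(0, 1), k = 2,
                                 k_neighbors = 3, seed = 9)
  expect_s3_class(sw, "hfo_sweep")
  expect_identical(nrow(sw), 4L)
  expect_identical(nrow(dplyr::distinct(sw[, c("n_layers", "factor")])), 4L)
  expect_setequal(sw$n_layers, c(1, 2))
  expect_setequal(sw$factor, c(0, 1))
  expect_true(all(sw$leakage_ok))
  expect_true(all(sw$tp + sw$fp + sw$tn + sw$fn == 16))
})

test_that("sweep results round-trip through tab-delimited text", {
  sw <- structure(tibble::tibble(model = "TransHFO", n_layers = 1,
                                 factor = 0, k = 2, seed = 1L,
                                 tp = 4, fp = 1, tn = 3, fn = 0,
                                 accuracy = 7 / 8, precision = 0.8,
                                 sensitivity = 1, specificity = 0.75,
                                 f_score = 8 / 9, degenerate = FALSE,
                                 leakage_ok = TRUE),
                  class = c("hfo_sweep", class(tibble::tibble())))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(sw, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$accuracy, sw$accuracy)
  expect_identical(nrow(back), 1L)
})

test_that("the bundled reference table satisfies the F-score identity", {
  ref <- reference_detector_metrics()
  expect_identical(nrow(ref), 5L)
  expect_true(all(c("precision", "sensitivity", "f_score") %in% names(ref)))
  recomputed <- round(2 * ref$precision * ref$sensitivity /
                        (ref$precision + ref$sensitivity), 4)
  expect_equal(recomputed, round(ref$f_score, 4), tolerance = 1e-12)
})
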