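#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy / glance methods for fitted detectors and results
#'
#' `tidy()` returns the per-unit detail of an object (per-epoch losses for a
#' network fit, per-fold confusion counts for a cross-validation result);
#' `glance()` returns a one-row summary.
#'
#' @param x A `transhfo_model`, `hfo_lr`, `hfo_ssae` or `cv_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name transhfo-tidiers
NULL

#' @rdname transhfo-tidiers
#' @export
tidy.transhfo_model <- function(x, ...) {
  tibble(epoch = seq_along(x$history), loss = x$history)
}

#' @rdname transhfo-tidiers
#' @export
glance.transhfo_model <- function(x, ...) {
  tibble(model = if (x$config$sublayer == "attention") "TransHFO" else "ResDen",
         n_layers = x$config$n_layers, n_heads = x$config$n_heads,
         d_model = x$config$d_model,
         n_parameters = length(flatten_params(x$params)),
         epochs = length(x$history), final_loss = tail(x$history, 1))
}

#' @rdname transhfo-tidiers
#' @export
tidy.hfo_lr <- function(x, ...) {
  tibble(term = c("(Intercept)", paste0("s", seq_len(x$n_points))),
         estimate = as.numeric(x$beta))
}

#' @rdname transhfo-tidiers
#' @export
glance.hfo_lr <- function(x, ...) {
  tibble(model = "LR", n_parameters = length(x$beta),
         n_train = x$n_train, converged = x$converged)
}

#' @rdname transhfo-tidiers
#' @export
tidy.hfo_ssae <- function(x, ...) {
  purrr::imap_dfr(x$pretrain_history, function(h, i) {
    tibble(layer = i, epoch = seq_along(h), reconstruction_loss = h)
  })
}

#' @rdname transhfo-tidiers
#' @export
glance.hfo_ssae <- function(x, ...) {
  tibble(model = "SMO",
         hidden = paste(x$config$hidden_sizes, collapse = "-"),
         sparsity_proportion = x$config$sparsity_proportion,
         l2_weight = x$config$l2_weight,
         finetune_epochs = length(x$val_history),
         final_val_loss = tail(x$val_history, 1))
}

#' @rdname transhfo-tidiers
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_cols(x$folds,
                   purrr::map_dfr(seq_len(nrow(x$folds)), function(i) {
                     compute_metrics(x$folds[i, ])
                   }))
}

#' @rdname transhfo-tidiers
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(tibble(model = x$model, k = x$k),
                   as_tibble(x$counts), x$metrics,
                   tibble(leakage_ok = x$leakage_ok))
}

#' Plot a depth-by-augmentation sweep
#'
#' One line per augmentation factor, metric against network depth N.
#'
#' @param object An `hfo_sweep` tibble.
#' @param metric Which metric column to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hfo_sweep <- function(object, metric = "accuracy", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n_layers,
                               y = .data[[metric]],
                               colour = factor(.data$factor))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stacked layers N", y = metric,
                  colour = "augmentation\nfactor") +
    ggplot2::theme_minimal()
}

#' Plot per-fold accuracy of a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold),
                                  y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$metrics$accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = paste0(object$model, ", ", object$k, "-fold CV")) +
    ggplot2::theme_minimal()
}

#' Plot example segments from a dataset
#'
#' Faceted waveform traces, useful for eyeballing simulated bursts against
#' background-only segments.
#'
#' @param ds A segment dataset tibble.
#' @param n Number of segments to draw (taken evenly across classes).
#' @return A ggplot object.
#' @export
plot_segments <- function(ds, n = 6) {
  validate_segments(ds)
  n_classes <- max(1L, length(unique(ds$label)))
  picked <- ds |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = ceiling(n / n_classes)) |>
    dplyr::ungroup() |>
    dplyr::slice_head(n = n)
  long <- picked |>
    dplyr::mutate(panel = paste0("#", .data$sample_id, " ", .data$label)) |>
    dplyr::select("panel", "samples", "fs") |>
    tidyr::unnest_longer("samples", values_to = "amplitude") |>
    dplyr::group_by(.data$panel) |>
    dplyr::mutate(time = (dplyr::row_number() - 1) / .data$fs) |>
    dplyr::ungroup()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}
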