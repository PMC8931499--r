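#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), so the filtered signal has zero phase lag and
#' oscillatory events are not shifted in time. The default band is the HFO
#' band, 80-500 Hz.
#'
#' @param x Numeric waveform.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order of the underlying one-pass filter
#'   (default 4; the forward-backward pass doubles the effective order).
#' @return Filtered waveform, same length as `x`.
#' @export
bandpass <- function(x, low = 80, high = 500, fs = 2400, order = 4) {
  if (low <= 0 || low >= high) abort("need 0 < low < high")
  if (high >= fs / 2) abort("high band edge must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Split a continuous recording into fixed-length segments
#'
#' Applies a moving window of `window` samples advancing by `stride` samples
#' to every channel. Per channel, segments start at samples
#' 0, stride, 2*stride, ...; the number of segments per channel is
#' `floor((L - window) / stride) + 1`. Returned segments are `"UNLABELED"`
#' and carry their channel and onset time so detections can be mapped back.
#'
#' @param rec A `meg_recording` (see [simulate_recording()]).
#' @param window Window length in samples; should equal the classifier's
#'   training segment length.
#' @param stride Step in samples (default `window`, i.e. non-overlapping).
#' @return A segment dataset tibble (possibly empty, with a warning, if the
#'   recording is shorter than one window).
#' @export
segment_recording <- function(rec, window, stride = window) {
  stopifnot(inherits(rec, "meg_recording"))
  if (window <= 0 || stride <= 0) abort("window and stride must be positive")
  L <- ncol(rec$data)
  if (window > L) {
    warn("recording is shorter than one window; returning an empty dataset")
    return(segment_dataset(matrix(numeric(0), 0, 0)))
  }
  starts <- seq(1L, L - window + 1L, by = stride)
  rows <- purrr::map(seq_len(nrow(rec$data)), function(ch) {
    segs <- lapply(starts, function(s) rec$data[ch, s:(s + window - 1L)])
    segment_dataset(segs, label = "UNLABELED", fs = rec$fs, source = "real",
                    channel_id = rec$channel_names[ch],
                    start_time = (starts - 1) / rec$fs)
  })
  out <- dplyr::bind_rows(rows)
  out$sample_id <- seq_len(nrow(out))
  out
}

#' Z-score a segment
#'
#' Centres and scales a waveform to zero mean and unit standard deviation.
#' A constant (zero-variance) segment maps to all zeros instead of dividing
#' by zero. Idempotent on non-degenerate input.
#'
#' @param x Numeric waveform of length > 1.
#' @return Normalized waveform.
#' @export
normalize_segment <- function(x) {
  if (length(x) < 2L) abort("a segment must have at least 2 samples")
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Band-pass filter a whole recording in place
#'
#' Filtering is applied to the continuous signal *before* segmentation, so
#' window edges do not introduce filter transients inside segments.
#'
#' @inheritParams bandpass
#' @param rec A `meg_recording`.
#' @return The recording with every channel filtered.
#' @export
bandpass_recording <- function(rec, low = 80, high = 500, order = 4) {
  stopifnot(inherits(rec, "meg_recording"))
  rec$data <- t(apply(rec$data, 1, bandpass, low = low, high = high,
                      fs = rec$fs, order = order))
  rec
}

#' Preprocess a segment dataset for classification
#'
#' The classification front end: per-segment band-pass to the HFO band
#' followed by per-segment z-scoring (attention layers are scale-sensitive,
#' so inputs are standardized). Both steps can be disabled.
#'
#' @param ds A segment dataset tibble.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order.
#' @param filter,normalize Logical switches for the two steps.
#' @return The dataset with transformed waveforms.
#' @examples
#' ds <- simulate_dataset(3, 3, seed = 1) |> preprocess_segments()
#' @export
preprocess_segments <- function(ds, low = 80, high = 500, order = 4,
                                filter = TRUE, normalize = TRUE) {
  validate_segments(ds)
  if (nrow(ds) == 0L) return(ds)
  ds$samples <- purrr::map2(ds$samples, ds$fs, function(x, fs) {
    if (filter) x <- bandpass(x, low = low, high = high, fs = fs, order = order)
    if (normalize) x <- normalize_segment(x)
    x
  })
  ds
}
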