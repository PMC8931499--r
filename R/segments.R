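#' Build a segment dataset tibble
#'
#' A segment dataset is an ordinary tibble with one row per fixed-length
#' signal segment and the columns `sample_id`, `samples` (list-column of
#' numeric waveforms, all the same length), `label` (`"HFO"`, `"NC"` or
#' `"UNLABELED"`), `fs` (sampling rate, Hz), `source` (`"real"`,
#' `"synthetic"` or `"virtual"`), `channel_id` and `start_time` (seconds).
#' All pipeline functions accept and return this shape, so calls chain with
#' the pipe.
#'
#' @param samples A numeric matrix (segments in rows) or a list of
#'   equal-length numeric vectors.
#' @param label Character vector (recycled) of segment labels.
#' @param fs Sampling rate in Hz.
#' @param source Provenance tag (recycled): `"real"`, `"synthetic"` or
#'   `"virtual"`.
#' @param channel_id Channel identifier (recycled).
#' @param start_time Segment onset within its recording, seconds (recycled).
#' @return A tibble with one row per segment.
#' @examples
#' segment_dataset(matrix(rnorm(40), nrow = 2), label = c("HFO", "NC"), fs = 2400)
#' @export
segment_dataset <- function(samples, label = "UNLABELED", fs = 2400,
                            source = "synthetic", channel_id = "ch1",
                            start_time = 0) {
  if (is.matrix(samples)) {
    samples <- lapply(seq_len(nrow(samples)), function(i) unname(samples[i, ]))
  }
  if (!is.list(samples)) samples <- list(as.numeric(samples))
  n <- length(samples)
  ds <- tibble(
    sample_id = seq_len(n),
    samples = samples,
    label = rep_len(as.character(label), n),
    fs = rep_len(as.numeric(fs), n),
    source = rep_len(as.character(source), n),
    channel_id = rep_len(as.character(channel_id), n),
    start_time = rep_len(as.numeric(start_time), n)
  )
  validate_segments(ds)
  ds
}

#' Validate a segment dataset
#'
#' Checks the invariants every pipeline step relies on: required columns,
#' equal segment lengths, finite samples, and recognized label/source values.
#' Called internally by the constructors; exported for defensive use at
#' module boundaries.
#'
#' @param ds A segment dataset tibble.
#' @return `ds`, invisibly, if valid; otherwise an error.
#' @export
validate_segments <- function(ds) {
  needed <- c("sample_id", "samples", "label", "fs", "source",
              "channel_id", "start_time")
  missing <- setdiff(needed, names(ds))
  if (length(missing)) {
    abort(paste0("segment dataset is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(ds) == 0L) return(invisible(ds))
  len <- lengths(ds$samples)
  if (length(unique(len)) != 1L) {
    abort("all segments must have the same length")
  }
  if (!all(vapply(ds$samples, function(x) all(is.finite(x)), logical(1)))) {
    abort("segment samples must all be finite")
  }
  if (!all(ds$label %in% c("HFO", "NC", "UNLABELED"))) {
    abort('labels must be "HFO", "NC" or "UNLABELED"')
  }
  if (!all(ds$source %in% c("real", "synthetic", "virtual"))) {
    abort('source must be "real", "synthetic" or "virtual"')
  }
  invisible(ds)
}

#' Stack a segment dataset into a numeric matrix
#'
#' @param ds A segment dataset tibble.
#' @return A numeric matrix, one row per segment.
#' @export
segment_matrix <- function(ds) {
  if (nrow(ds) == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  do.call(rbind, ds$samples)
}

# Number of samples per segment (0 for an empty dataset).
segment_length <- function(ds) {
  if (nrow(ds) == 0L) return(0L)
  length(ds$samples[[1]])
}

#' Class counts of a segment dataset
#'
#' @param ds A segment dataset tibble.
#' @return A tibble with columns `label` and `n`.
#' @export
class_counts <- function(ds) {
  dplyr::count(ds, .data$label)
}

#' Write / read a segment dataset as plain CSV
#'
#' One row per segment: the waveform in columns `s1..sT`, then the metadata
#' columns, with `label` last. The round trip preserves waveforms to full
#' double precision.
#'
#' @param ds A segment dataset tibble.
#' @param path File path.
#' @return `write_segments_csv()` returns `path` invisibly;
#'   `read_segments_csv()` returns a segment dataset tibble.
#' @export
write_segments_csv <- function(ds, path) {
  validate_segments(ds)
  mat <- segment_matrix(ds)
  wide <- as_tibble(mat, .name_repair = ~ paste0("s", seq_along(.x)))
  out <- dplyr::bind_cols(
    wide,
    ds[, c("fs", "source", "channel_id", "start_time", "label")]
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  scols <- grep("^s[0-9]+$", names(raw), value = TRUE)
  scols <- scols[order(as.integer(sub("^s", "", scols)))]
  mat <- as.matrix(raw[, scols])
  segment_dataset(mat,
                  label = raw$label, fs = raw$fs, source = raw$source,
                  channel_id = raw$channel_id, start_time = raw$start_time)
}

#' Write / read a ground-truth event list as tab-delimited text
#'
#' BED-like columns: `channel`, `onset_s`, `duration_s`, `freq_hz`,
#' `amplitude`, `envelope`.
#'
#' @param events A tibble of events (as stored in a simulated recording's
#'   `event_truth`).
#' @param path File path.
#' @return `write_events_tsv()` returns `path` invisibly;
#'   `read_events_tsv()` returns a tibble.
#' @export
write_events_tsv <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
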