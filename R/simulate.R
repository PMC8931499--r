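#' HFO burst parameters
#'
#' Parameters of a single simulated high-frequency oscillatory burst. The
#' burst is an envelope-windowed sinusoid whose centre frequency must lie in
#' the HFO band (80-500 Hz) and which must contain at least four oscillatory
#' cycles (`duration * center_freq >= 4`), so that what is inserted is a
#' genuine oscillation rather than a sharp transient.
#'
#' `amplitude` is a dimensionless SNR scale: segment backgrounds are
#' calibrated so their 80-500 Hz band RMS is 1, and the burst's peak envelope
#' amplitude equals `amplitude` on that scale.
#'
#' @param center_freq Centre frequency in Hz, within \[80, 500\].
#' @param duration Burst duration in seconds.
#' @param amplitude Peak envelope amplitude (SNR units, >= 0).
#' @param envelope `"gaussian"` (sd = duration/6) or `"hann"`.
#' @param onset Onset in seconds (used when placing events in recordings).
#' @return An object of class `hfo_event_params`.
#' @export
hfo_event_params <- function(center_freq = 150, duration = 0.08,
                             amplitude = 3, envelope = c("gaussian", "hann"),
                             onset = 0) {
  envelope <- match.arg(envelope)
  if (center_freq < 80 || center_freq > 500) {
    abort("center_freq must lie in the HFO band [80, 500] Hz")
  }
  if (duration <= 0) abort("duration must be positive")
  if (amplitude < 0) abort("amplitude must be non-negative")
  if (duration * center_freq < 4) {
    abort("duration * center_freq must be >= 4 (at least four cycles)")
  }
  if (onset < 0) abort("onset must be non-negative")
  structure(list(center_freq = center_freq, duration = duration,
                 amplitude = amplitude, envelope = envelope, onset = onset),
            class = "hfo_event_params")
}

#' Background noise parameters
#'
#' The simulated background is the sum of a 1/f^alpha ("pink") component and
#' white Gaussian noise, the standard first-order model of resting
#' neurophysiological spectra. At least one component must be non-zero for
#' non-degenerate noise (enforced where noise is actually required).
#'
#' @param pink_exponent Spectral slope alpha (>= 0) of the 1/f^alpha
#'   component.
#' @param pink_sd Standard deviation of the pink component (0 disables it).
#' @param white_sd Standard deviation of the white component.
#' @param seed Optional integer seed used by [simulate_background()].
#' @return An object of class `background_params`.
#' @export
background_params <- function(pink_exponent = 1, pink_sd = 1, white_sd = 0.5,
                              seed = NULL) {
  if (pink_exponent < 0 || pink_sd < 0 || white_sd < 0) {
    abort("background parameters must be non-negative")
  }
  structure(list(pink_exponent = pink_exponent, pink_sd = pink_sd,
                 white_sd = white_sd, seed = seed),
            class = "background_params")
}

#' Simulate one HFO burst waveform
#'
#' Generates `round(duration * fs)` samples of an envelope-windowed sinusoid
#' at the configured centre frequency. The phase is uniform-random unless
#' given explicitly; with `amplitude = 0` the result is an all-zero vector of
#' the correct length.
#'
#' @param params An [hfo_event_params()] object.
#' @param fs Sampling rate in Hz; must exceed twice the centre frequency.
#' @param seed Optional integer seed (fixes the random phase).
#' @param phase Optional phase in radians; overrides the random draw.
#' @return A numeric waveform vector.
#' @export
simulate_hfo_burst <- function(params, fs, seed = NULL, phase = NULL) {
  stopifnot(inherits(params, "hfo_event_params"))
  if (fs <= 2 * params$center_freq) {
    abort("fs must exceed twice the burst centre frequency (Nyquist)")
  }
  n <- round(params$duration * fs)
  with_seed_or_current(seed, {
    if (is.null(phase)) phase <- runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / fs
    mid <- (n - 1) / (2 * fs)
    env <- switch(params$envelope,
      gaussian = exp(-0.5 * ((t - mid) / (params$duration / 6))^2),
      hann = 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
    )
    params$amplitude * env * sin(2 * pi * params$center_freq * t + phase)
  })
}

# 1/f^alpha noise via frequency-domain shaping of white noise, standardized
# to unit SD. Deterministic given the current RNG state.
pink_noise <- function(n, alpha) {
  x <- rnorm(n)
  if (alpha == 0) return(x / stats::sd(x))
  X <- fft(x)
  k <- seq_len(n) - 1
  kf <- pmin(k, n - k)            # symmetric bin index, keeps output real
  gain <- c(0, kf[-1]^(-alpha / 2))
  y <- Re(fft(X * gain, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate background noise
#'
#' Sum of a 1/f^alpha-shaped component and white Gaussian noise, per
#' [background_params()]. With both components disabled the result is an
#' all-zero vector.
#'
#' @param n_samples Number of samples (> 0).
#' @param fs Sampling rate in Hz (metadata only; the spectral shape is
#'   defined per FFT bin).
#' @param params A [background_params()] object; its `seed` field, when
#'   non-NULL, makes the draw reproducible.
#' @return A numeric waveform vector of length `n_samples`.
#' @export
simulate_background <- function(n_samples, fs = 2400,
                                params = background_params()) {
  stopifnot(inherits(params, "background_params"))
  if (n_samples <= 0) abort("n_samples must be positive")
  n <- as.integer(n_samples)
  with_seed_or_current(params$seed, {
    out <- numeric(n)
    if (params$pink_sd > 0) {
      out <- out + params$pink_sd * pink_noise(n, params$pink_exponent)
    }
    if (params$white_sd > 0) out <- out + params$white_sd * rnorm(n)
    out
  })
}

# Background calibrated so its 80-500 Hz band RMS is exactly 1 (defines the
# SNR scale that burst amplitudes are quoted on). Degenerate all-zero noise
# passes through unscaled.
calibrated_background <- function(n, fs, params) {
  bg <- simulate_background(n, fs, params)
  band_rms <- sqrt(mean(bandpass(bg, low = 80, high = 500, fs = fs)^2))
  if (band_rms > 0) bg / band_rms else bg
}

#' Simulate one labelled segment
#'
#' An `"NC"` segment is calibrated background only; an `"HFO"` segment is the
#' same background plus one burst inserted at a uniform-random interior
#' position with uniform-random phase. Because the background is drawn before
#' the burst placement, an HFO segment with `amplitude = 0` is bit-identical
#' to the NC segment generated from the same seed.
#'
#' @param kind `"HFO"` or `"NC"`.
#' @param hfo An [hfo_event_params()] object (ignored for `"NC"`).
#' @param bg A [background_params()] object.
#' @param n_points Segment length in samples (default 2000).
#' @param fs Sampling rate in Hz (default 2400).
#' @param seed Optional integer seed.
#' @return A one-row segment dataset tibble.
#' @export
simulate_segment <- function(kind = c("HFO", "NC"), hfo = hfo_event_params(),
                             bg = background_params(), n_points = 2000,
                             fs = 2400, seed = NULL) {
  kind <- match.arg(kind)
  if (n_points <= 0) abort("n_points must be positive")
  if (fs <= 1000) abort("fs must exceed 1000 Hz so the HFO band is below Nyquist")
  nb <- round(hfo$duration * fs)
  if (kind == "HFO" && nb > n_points) {
    abort("burst duration exceeds the segment length")
  }
  bg_local <- bg
  bg_local$seed <- NULL
  x <- with_seed_or_current(seed, {
    sig <- calibrated_background(n_points, fs, bg_local)
    if (kind == "HFO") {
      onset <- sample.int(n_points - nb + 1L, 1L)
      phase <- runif(1, 0, 2 * pi)
      burst <- simulate_hfo_burst(hfo, fs, phase = phase)
      sig[onset:(onset + nb - 1L)] <- sig[onset:(onset + nb - 1L)] + burst
    }
    sig
  })
  segment_dataset(list(x), label = kind, fs = fs, source = "synthetic")
}

#' Simulate a ground-truthed segment dataset
#'
#' Generates a two-class dataset of fixed-length segments emulating a
#' gold-standard HFO/NC collection: each HFO segment carries one burst whose
#' centre frequency and duration are jittered uniformly within the given
#' ranges; NC segments are background only. The default class sizes (101 +
#' 101) and segment shape (2000 points, 2400 Hz) match the gold-standard
#' tensor this simulator emulates.
#'
#' @param n_hfo,n_nc Class sizes (>= 0).
#' @param amplitude Burst SNR amplitude shared by all HFO segments.
#' @param freq_range Burst centre-frequency jitter range, Hz.
#' @param duration_range Burst duration jitter range, seconds.
#' @param envelope Burst envelope shape.
#' @param bg A [background_params()] object.
#' @param n_points Segment length in samples.
#' @param fs Sampling rate, Hz.
#' @param seed Optional integer seed.
#' @return A segment dataset tibble with `n_hfo + n_nc` rows.
#' @examples
#' ds <- simulate_dataset(5, 5, seed = 1)
#' class_counts(ds)
#' @export
simulate_dataset <- function(n_hfo = 101, n_nc = 101, amplitude = 3,
                             freq_range = c(100, 300),
                             duration_range = c(0.05, 0.12),
                             envelope = "gaussian",
                             bg = background_params(), n_points = 2000,
                             fs = 2400, seed = NULL) {
  if (n_hfo < 0 || n_nc < 0) abort("class sizes must be non-negative")
  n <- n_hfo + n_nc
  if (n == 0L) {
    return(segment_dataset(matrix(numeric(0), 0, 0))[0, ])
  }
  rows <- with_seed_or_current(seed, {
    seg_seeds <- sample.int(.Machine$integer.max - 1L, n)
    freqs <- runif(n_hfo, freq_range[1], freq_range[2])
    durs <- runif(n_hfo, duration_range[1], duration_range[2])
    kinds <- c(rep("HFO", n_hfo), rep("NC", n_nc))
    purrr::map(seq_len(n), function(i) {
      ev <- if (kinds[i] == "HFO") {
        hfo_event_params(center_freq = freqs[i], duration = durs[i],
                         amplitude = amplitude, envelope = envelope)
      } else {
        hfo_event_params(amplitude = 0)
      }
      simulate_segment(kinds[i], hfo = ev, bg = bg, n_points = n_points,
                       fs = fs, seed = seg_seeds[i])
    })
  })
  out <- dplyr::bind_rows(rows)
  out$sample_id <- seq_len(nrow(out))
  out
}

#' Simulate a continuous multi-channel recording
#'
#' Continuous calibrated background per channel, with bursts added linearly
#' at the stated onsets (overlapping events simply sum). The ground-truth
#' event list is stored on the returned object for downstream scoring.
#'
#' @param duration Recording length in seconds.
#' @param events A tibble with columns `channel`, `onset_s`, `freq_hz`,
#'   `duration_s`, `amplitude` and optionally `envelope`; or `NULL` for an
#'   event-free recording.
#' @param bg A [background_params()] object.
#' @param fs Sampling rate, Hz (> 1000 so the HFO band is below Nyquist).
#' @param n_channels Number of channels.
#' @param seed Optional integer seed.
#' @return An object of class `meg_recording`: a list with `data`
#'   (channels x samples matrix), `fs`, `channel_names` and `event_truth`.
#' @export
simulate_recording <- function(duration, events = NULL,
                               bg = background_params(), fs = 2400,
                               n_channels = 1, seed = NULL) {
  if (fs <= 1000) abort("fs must exceed 1000 Hz so the HFO band is below Nyquist")
  n <- round(duration * fs)
  if (is.null(events)) {
    events <- tibble(channel = integer(), onset_s = numeric(),
                     duration_s = numeric(), freq_hz = numeric(),
                     amplitude = numeric(), envelope = character())
  }
  if (!"envelope" %in% names(events)) {
    events$envelope <- rep("gaussian", nrow(events))
  }
  if (nrow(events) > 0 &&
      any(events$onset_s + events$duration_s > duration)) {
    abort("every event must end before the recording does")
  }
  bg_local <- bg
  bg_local$seed <- NULL
  data <- with_seed_or_current(seed, {
    mat <- do.call(rbind, lapply(seq_len(n_channels), function(ch) {
      calibrated_background(n, fs, bg_local)
    }))
    if (nrow(events) > 0) {
      for (i in seq_len(nrow(events))) {
        ev <- hfo_event_params(center_freq = events$freq_hz[i],
                               duration = events$duration_s[i],
                               amplitude = events$amplitude[i],
                               envelope = events$envelope[i],
                               onset = events$onset_s[i])
        burst <- simulate_hfo_burst(ev, fs, phase = runif(1, 0, 2 * pi))
        start <- round(events$onset_s[i] * fs) + 1L
        idx <- start:(start + length(burst) - 1L)
        ch <- as.integer(events$channel[i])
        mat[ch, idx] <- mat[ch, idx] + burst
      }
    }
    mat
  })
  structure(
    list(data = data, fs = fs,
         channel_names = paste0("ch", seq_len(n_channels)),
         event_truth = events),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channel(s) x %d samples @ %g Hz, %d truth event(s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$event_truth)))
  invisible(x)
}
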