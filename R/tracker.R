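#' Tracker configuration
#'
#' Bundles every tunable parameter of the f0 tracker. The defaults target
#' canary-like song at 44.1 kHz: a 1024-sample Hann window (23.2 ms, below the
#' 33 ms needed to resolve a 30 Hz syllabic rate) with 50% overlap, the
#' 800-8000 Hz canary band, and a silence gate at 5% of the recording's peak
#' envelope.
#'
#' @param window Analysis window length in samples.
#' @param overlap Samples shared by consecutive windows (`0 <= overlap < window`).
#' @param window_function Taper: `"hann"` (default), `"hamming"`,
#'   `"blackman"`, or `"rectangular"`.
#' @param f_min,f_max Frequency band of interest in Hz; peaks are picked only
#'   inside it.
#' @param threshold Silence-gate threshold: a fraction of the peak envelope in
#'   relative mode, an amplitude in absolute mode.
#' @param threshold_mode `"relative"` (default) or `"absolute"`.
#' @param smooth_ms Envelope moving-average width in milliseconds.
#' @param channel_policy How stereo input is collapsed; see [to_mono()].
#' @param max_syllabic_rate Fastest syllabic rate (Hz) the window must
#'   resolve; used only for validation warnings.
#' @return An object of class `tracker_config`.
#' @examples
#' tracker_config(window = 512, f_min = 1000, f_max = 6000)
#' @export
tracker_config <- function(window = 1024L, overlap = 512L,
                           window_function = "hann",
                           f_min = 800, f_max = 8000,
                           threshold = 0.05,
                           threshold_mode = c("relative", "absolute"),
                           smooth_ms = 5, channel_policy = "average",
                           max_syllabic_rate = 30) {
  threshold_mode <- match.arg(threshold_mode)
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (window < 2L) stop("configuration error: window must be >= 2 samples")
  if (overlap < 0L || overlap >= window)
    stop("configuration error: overlap must satisfy 0 <= overlap < window")
  if (f_min < 0 || f_min >= f_max)
    stop("configuration error: need 0 <= f_min < f_max")
  if (threshold_mode == "relative" && (threshold < 0 || threshold > 1))
    stop("configuration error: relative threshold must lie in [0, 1]")
  if (threshold < 0) stop("configuration error: threshold must be >= 0")
  if (smooth_ms < 0) stop("configuration error: smooth_ms must be >= 0")
  if (max_syllabic_rate <= 0)
    stop("configuration error: max_syllabic_rate must be > 0")
  taper_window(window_function, 8L)  # validates the name
  structure(list(window = window, overlap = overlap,
                 window_function = window_function,
                 f_min = f_min, f_max = f_max,
                 threshold = threshold, threshold_mode = threshold_mode,
                 smooth_ms = smooth_ms, channel_policy = channel_policy,
                 max_syllabic_rate = max_syllabic_rate),
            class = "tracker_config")
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("<tracker_config>\n")
  cat(sprintf("  window %d, overlap %d (%s)\n", x$window, x$overlap,
              x$window_function))
  cat(sprintf("  band %g-%g Hz; threshold %g (%s); smooth %g ms\n",
              x$f_min, x$f_max, x$threshold, x$threshold_mode, x$smooth_ms))
  cat(sprintf("  channel policy %s; max syllabic rate %g Hz\n",
              as.character(x$channel_policy), x$max_syllabic_rate))
  invisible(x)
}

#' Validate a configuration against a sample rate
#'
#' Returns human-readable warnings (never errors) for soft problems: a window
#' too long to resolve the stated syllabic rate, a band edge beyond Nyquist
#' (the tracker clips it), or a frequency resolution too coarse for the band
#' (fewer than ~4 bins across it). Hard invariant violations are raised by
#' [tracker_config()] itself.
#'
#' @param config A `tracker_config`.
#' @param sample_rate Sample rate of the signal to be analyzed, in Hz.
#' @return Character vector of warning messages (length 0 when clean).
#' @export
validate_config <- function(config, sample_rate) {
  stopifnot(inherits(config, "tracker_config"))
  warnings <- character(0)
  dur <- config$window / sample_rate
  bound <- time_resolution_bound(config$max_syllabic_rate)
  if (dur >= bound)
    warnings <- c(warnings, sprintf(
      "window duration %.1f ms >= %.1f ms needed to resolve a %g Hz syllabic rate",
      dur * 1000, bound * 1000, config$max_syllabic_rate))
  nyquist <- sample_rate / 2
  f_max <- config$f_max
  if (f_max > nyquist) {
    warnings <- c(warnings, sprintf(
      "f_max %g Hz exceeds the Nyquist frequency; clipped to %g Hz",
      f_max, nyquist))
    f_max <- nyquist
  }
  bin_width <- sample_rate / config$window
  if (bin_width > (f_max - config$f_min) / 4)
    warnings <- c(warnings, sprintf(
      "frequency bin width %.1f Hz is coarse for the %g-%g Hz band",
      bin_width, config$f_min, f_max))
  warnings
}

#' Maximum-intensity frequency per time bin
#'
#' The core of the tracker: for each spectrogram column, the frequency of the
#' most intense bin and its power. Ties are broken toward the lowest
#' frequency, which biases toward the fundamental.
#'
#' @param grid A `spectrogram` (typically band-restricted first).
#' @return List with `frequency` (Hz) and `power`, one value per time bin.
#' @export
peak_frequency_per_bin <- function(grid) {
  stopifnot(inherits(grid, "spectrogram"))
  if (length(grid$times) == 0L || length(grid$freqs) == 0L)
    stop("insufficient data: empty spectrogram")
  idx <- max.col(t(grid$power), ties.method = "first")
  list(frequency = grid$freqs[idx],
       power = grid$power[cbind(idx, seq_along(idx))])
}

#' Track the fundamental frequency of a tonal sound
#'
#' End-to-end f0 estimation for tonal vocalizations: the signal is collapsed
#' to mono, a short-time spectrogram is computed and restricted to the
#' configured band, and each time bin's maximum-intensity frequency is taken
#' as its f0 estimate. In parallel, the amplitude envelope is reduced to a
#' per-bin level and thresholded; bins below the gate are marked silent and
#' get `NaN` instead of a frequency, so silence and background noise do not
#' contaminate the track.
#'
#' When a harmonic carries more power than the fundamental inside the band,
#' the tracker reports the harmonic: the band filter is the only mitigation.
#' No peak interpolation is performed, so the accuracy contract is one
#' frequency-bin width (`sample_rate / window`).
#'
#' @param x An [audio_signal] or the path to a WAV file.
#' @param config A [tracker_config()].
#' @return An object of class `f0_track`: `times` (bin centers, s), `f0_hz`
#'   (`NaN` where silent), `voiced` (logical), `peak_power`, `bin_levels`
#'   (envelope level per bin), `threshold_value` (resolved absolute gate),
#'   plus the resolved `config`, validation `warnings`, and the mono `signal`
#'   and band-restricted `grid` used (for plotting). Soft configuration
#'   problems are also emitted as R warnings.
#' @examples
#' tone <- make_tone(2000, 0.5, 44100)
#' trk <- track_f0(tone)
#' summary(trk)
#' @export
track_f0 <- function(x, config = tracker_config()) {
  if (is.character(x)) x <- read_wav(x)
  stopifnot(inherits(x, "audio_signal"), inherits(config, "tracker_config"))

  mono <- to_mono(x, config$channel_policy)
  msgs <- validate_config(config, mono$sample_rate)
  for (m in msgs) warning(m, call. = FALSE)
  f_max <- min(config$f_max, mono$sample_rate / 2)

  grid <- compute_spectrogram(mono, window = config$window,
                              overlap = config$overlap,
                              window_function = config$window_function)
  band <- restrict_band(grid, config$f_min, f_max)
  peaks <- peak_frequency_per_bin(band)

  env <- compute_envelope(mono, smooth_ms = config$smooth_ms)
  levels <- envelope_at_bins(env, band)
  voiced <- voiced_mask(levels, config$threshold, config$threshold_mode)
  t_abs <- if (config$threshold_mode == "relative")
    config$threshold * max(levels) else config$threshold

  f0 <- peaks$frequency
  f0[!voiced] <- NaN

  structure(list(times = band$times, f0_hz = f0, voiced = voiced,
                 peak_power = peaks$power, bin_levels = levels,
                 threshold_value = t_abs, config = config,
                 warnings = msgs, signal = mono, grid = band),
            class = "f0_track")
}
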