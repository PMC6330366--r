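#' Short-time Fourier spectrogram (sonogram)
#'
#' Splits a mono signal into consecutive windows advancing by
#' `hop = window - overlap` samples, tapers each segment with the chosen
#' window function, transforms it with the FFT (no zero padding) and stores
#' the squared magnitude of the non-negative frequencies as one column of the
#' power matrix. Segments are kept statistically independent: there is no
#' inter-column averaging or detrending. Trailing samples that do not fill a
#' whole window are discarded, so the number of time bins is
#' `floor((n_samples - window) / hop) + 1`.
#'
#' Power is stored on a linear scale (raw squared FFT magnitude). The per-bin
#' peak frequency is invariant under any monotone rescaling of the power, so
#' this choice cannot affect the tracker; decibels are used only for plotting.
#'
#' @param x A mono [audio_signal].
#' @param window Analysis window length in samples (>= 2).
#' @param overlap Samples shared by consecutive windows; `0 <= overlap < window`.
#' @param window_function One of `"hann"`, `"hamming"`, `"blackman"`,
#'   `"rectangular"`.
#' @return An object of class `spectrogram`: list with `times` (bin-center
#'   seconds, `(k*hop + window/2)/sample_rate`), `freqs` (Hz, `0` to Nyquist,
#'   spacing `sample_rate/window`), `power` (frequency-by-time matrix), and
#'   `meta` (window, hop, overlap, window_function, sample_rate).
#' @examples
#' s <- make_tone(1000, 1, 8000)
#' g <- compute_spectrogram(s, window = 256, overlap = 128)
#' g$freqs[which.max(g$power[, 1])]  # ~1000 Hz
#' @export
compute_spectrogram <- function(x, window = 1024L, overlap = 512L,
                                window_function = "hann") {
  stopifnot(inherits(x, "audio_signal"))
  if (n_channels(x) != 1L)
    stop("configuration error: spectrogram requires a mono signal; see to_mono()")
  window <- as.integer(window)
  overlap <- as.integer(overlap)
  if (window < 2L) stop("configuration error: window must be >= 2 samples")
  if (overlap < 0L || overlap >= window)
    stop("configuration error: overlap must satisfy 0 <= overlap < window")
  n <- length(x$samples)
  if (n < window)
    stop(sprintf("insufficient data: signal has %d samples but window is %d", n, window))

  hop <- window - overlap
  n_times <- (n - window) %/% hop + 1L
  w <- taper_window(window_function, window)

  idx <- outer(seq_len(window), (seq_len(n_times) - 1L) * hop, `+`)
  seg <- matrix(x$samples[idx], nrow = window) * w
  spec <- stats::mvfft(seg)
  n_freq <- window %/% 2L + 1L
  power <- Mod(spec[seq_len(n_freq), , drop = FALSE])^2

  sr <- x$sample_rate
  structure(list(
    times = ((seq_len(n_times) - 1L) * hop + window / 2) / sr,
    freqs = (seq_len(n_freq) - 1L) * sr / window,
    power = power,
    meta = list(window = window, hop = hop, overlap = overlap,
                window_function = window_function, sample_rate = sr)
  ), class = "spectrogram")
}

taper_window <- function(name, n) {
  name <- match.arg(name, c("hann", "hamming", "blackman", "rectangular"))
  k <- seq_len(n) - 1L
  switch(name,
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
    blackman = 0.42 - 0.5 * cos(2 * pi * k / (n - 1)) +
      0.08 * cos(4 * pi * k / (n - 1)),
    rectangular = rep(1, n)
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins (%.1f-%.1f Hz) x %d time bins; window %d, hop %d (%s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              x$meta$window, x$meta$hop, x$meta$window_function))
  invisible(x)
}

#' Restrict a spectrogram to a frequency band
#'
#' Keeps only the frequency rows with `f_min <= f <= f_max`; the time axis is
#' unchanged. Applied before peak picking this acts as the band filter that
#' keeps the tracker inside the species' singing range (800 Hz to 8 kHz for
#' the canary).
#'
#' @param grid A `spectrogram`.
#' @param f_min,f_max Band edges in Hz, `0 <= f_min < f_max`.
#' @return A `spectrogram` with the reduced frequency axis.
#' @export
restrict_band <- function(grid, f_min, f_max) {
  stopifnot(inherits(grid, "spectrogram"))
  if (f_min < 0 || f_min >= f_max)
    stop("configuration error: need 0 <= f_min < f_max")
  keep <- grid$freqs >= f_min & grid$freqs <= f_max
  if (!any(keep))
    stop(sprintf("configuration error: band [%g, %g] Hz contains no frequency bins",
                 f_min, f_max))
  grid$freqs <- grid$freqs[keep]
  grid$power <- grid$power[keep, , drop = FALSE]
  grid
}

#' Maximum analysis-window duration that resolves a syllabic rate
#'
#' Syllables produced at rate `r` per second are only separable when the
#' analysis window is shorter than `1/r` seconds. Canaries sing at 3-30
#' syllables per second, so the default tracker validation uses 30 Hz, giving
#' a bound of 1/30 s (33 ms).
#'
#' @param max_syllabic_rate Fastest syllabic rate to resolve, in Hz (> 0).
#' @return The bound in seconds; window durations must stay strictly below it.
#' @export
time_resolution_bound <- function(max_syllabic_rate) {
  if (!is.numeric(max_syllabic_rate) || length(max_syllabic_rate) != 1L ||
      max_syllabic_rate <= 0)
    stop("configuration error: max_syllabic_rate must be a positive number")
  1 / max_syllabic_rate
}
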