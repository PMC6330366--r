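#' Amplitude envelope of a signal
#'
#' Estimates the slowly varying amplitude of a mono signal as the magnitude of
#' its analytic signal (Hilbert envelope), smoothed by a centered moving
#' average. The envelope is the loudness gate the tracker uses to separate
#' song from silence.
#'
#' The analytic signal is built in the frequency domain: negative frequencies
#' are zeroed, positive ones doubled, and the inverse FFT taken; its modulus
#' is the instantaneous amplitude. The moving-average width is
#' `round(smooth_ms * sample_rate / 1000)` samples (at least 1); edges are
#' padded by replication so the output keeps the signal's length.
#'
#' @param x A mono [audio_signal].
#' @param smooth_ms Moving-average width in milliseconds (>= 0; 0 disables
#'   smoothing). Default 5 ms.
#' @return An object of class `envelope_trace`: list with `times` (seconds,
#'   one per sample) and `values` (non-negative amplitudes, same units as the
#'   samples).
#' @export
compute_envelope <- function(x, smooth_ms = 5) {
  stopifnot(inherits(x, "audio_signal"))
  if (n_channels(x) != 1L)
    stop("configuration error: envelope requires a mono signal; see to_mono()")
  if (smooth_ms < 0) stop("configuration error: smooth_ms must be >= 0")
  s <- x$samples
  n <- length(s)
  if (n < 1L) stop("insufficient data: empty signal")

  env <- Mod(analytic_signal(s))
  width <- max(1L, as.integer(round(smooth_ms * x$sample_rate / 1000)))
  if (width > 1L) env <- moving_average(env, width)
  env[env < 0] <- 0

  structure(list(times = (seq_len(n) - 1L) / x$sample_rate, values = env),
            class = "envelope_trace")
}

# Analytic signal via the FFT: zero the negative frequencies, double the
# strictly positive ones (DC and Nyquist kept once), inverse transform.
analytic_signal <- function(s) {
  n <- length(s)
  if (n == 1L) return(complex(real = s, imaginary = 0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(stats::fft(s) * h, inverse = TRUE) / n
}

# Centered moving average with edge replication; output length = input length.
moving_average <- function(v, width) {
  n <- length(v)
  lw <- (width - 1L) %/% 2L
  rw <- width - 1L - lw
  padded <- c(rep(v[1L], lw), v, rep(v[n], rw))
  out <- stats::filter(padded, rep(1 / width, width), sides = 1)
  as.numeric(out[width:(width + n - 1L)])
}

#' @export
print.envelope_trace <- function(x, ...) {
  cat(sprintf("<envelope_trace> %d samples, peak %.4g\n",
              length(x$values), max(x$values)))
  invisible(x)
}

#' Envelope level per spectrogram time bin
#'
#' Reduces the sample-rate envelope to one value per spectrogram column: the
#' maximum envelope value over that bin's window extent
#' `[k*hop, k*hop + window)`. The maximum (rather than the mean) is used so a
#' bin containing any part of a syllable onset counts as sound.
#'
#' @param env An `envelope_trace` computed from the same signal as `grid`.
#' @param grid A `spectrogram`.
#' @return Numeric vector, one non-negative level per time bin of `grid`.
#' @export
envelope_at_bins <- function(env, grid) {
  stopifnot(inherits(env, "envelope_trace"), inherits(grid, "spectrogram"))
  hop <- grid$meta$hop
  window <- grid$meta$window
  n_times <- length(grid$times)
  if ((n_times - 1L) * hop + window > length(env$values))
    stop("consistency error: spectrogram extends past the envelope")
  vapply(seq_len(n_times) - 1L,
         function(k) max(env$values[(k * hop + 1L):(k * hop + window)]),
         numeric(1))
}

#' Voiced/silent gate from per-bin envelope levels
#'
#' Marks a time bin voiced when its envelope level reaches the threshold
#' (comparison is `>=`, so threshold-attaining bins are voiced). In relative
#' mode the threshold is `r * max(levels)`, robust across recording gains; in
#' absolute mode it is the given amplitude. An all-zero input under relative
#' mode with `r > 0` is entirely silent.
#'
#' @param bin_levels Non-negative per-bin envelope levels
#'   (from [envelope_at_bins()]).
#' @param threshold Relative fraction in \[0, 1\] (`mode = "relative"`) or an
#'   absolute amplitude (`mode = "absolute"`).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return Logical vector: `TRUE` where voiced.
#' @export
voiced_mask <- function(bin_levels, threshold, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (any(bin_levels < 0)) stop("bin_levels must be non-negative")
  if (mode == "relative") {
    if (threshold < 0 || threshold > 1)
      stop("configuration error: relative threshold must lie in [0, 1]")
    peak <- max(bin_levels)
    if (peak == 0 && threshold > 0) return(rep(FALSE, length(bin_levels)))
    t_abs <- threshold * peak
  } else {
    if (threshold < 0)
      stop("configuration error: absolute threshold must be >= 0")
    t_abs <- threshold
  }
  bin_levels >= t_abs
}
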