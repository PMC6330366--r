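#' Sampled audio signal
#'
#' Container for a sampled waveform: amplitude values scaled to \[-1, 1\]
#' together with the sample rate. Mono signals hold a numeric vector;
#' multi-channel signals hold a frames-by-channels matrix.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel
#'   (frames in rows). Values must be finite.
#' @param sample_rate Sampling rate in Hz (samples per second), positive.
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * (0:999) / 8000), 8000)
#' n_channels(s)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (length(samples) < 1L) stop("empty input: signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("`samples` must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("configuration error: `sample_rate` must be a single positive number")
  if (is.matrix(samples) && ncol(samples) == 1L) samples <- drop(samples)
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_signal")
}

#' @rdname audio_signal
#' @param x An `audio_signal`.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  if (is.matrix(x$samples)) ncol(x$samples) else 1L
}

#' Number of frames (samples per channel) of an audio signal
#' @param x An `audio_signal`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
}

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @export
duration <- function(x) n_frames(x) / x$sample_rate

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d frames, %d channel(s), %g Hz (%.3f s)\n",
              n_frames(x), n_channels(x), x$sample_rate, duration(x)))
  invisible(x)
}

#' Convert a signal to mono
#'
#' Collapses a multi-channel signal to one channel. Policy `"average"` takes
#' the arithmetic mean across channels per frame; `"left"`/`"right"` select
#' channel 1/2; an integer selects that channel. Mono input is returned
#' unchanged whatever the policy.
#'
#' @param x An `audio_signal`.
#' @param policy `"average"` (default), `"left"`, `"right"`, or a channel index.
#' @return A mono `audio_signal`.
#' @export
to_mono <- function(x, policy = "average") {
  stopifnot(inherits(x, "audio_signal"))
  if (!is.matrix(x$samples)) return(x)
  k <- NULL
  if (is.numeric(policy)) {
    k <- as.integer(policy)
  } else {
    policy <- match.arg(policy, c("average", "left", "right"))
    if (policy == "average")
      return(audio_signal(rowMeans(x$samples), x$sample_rate))
    k <- if (policy == "left") 1L else 2L
  }
  if (k < 1L || k > ncol(x$samples))
    stop(sprintf("configuration error: channel %d out of range (signal has %d channels)",
                 k, ncol(x$samples)))
  audio_signal(x$samples[, k], x$sample_rate)
}
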