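# Synthetic canary-like fixtures: pure tones, linear sweeps, and syllable
# trains with known ground truth (onsets, offsets, f0 trajectories), so every
# tracker stage is testable without recordings.

#' Generate a pure tone
#'
#' @param f0 Frequency in Hz, `0 < f0 < sample_rate/2`.
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param amplitude Peak amplitude (dimensionless).
#' @return A mono [audio_signal] with samples `amplitude * sin(2*pi*f0*t)`.
#' @export
make_tone <- function(f0, duration, sample_rate, amplitude = 1) {
  make_chirp(f0, f0, duration, sample_rate, amplitude)
}

#' Generate a linear frequency sweep
#'
#' Instantaneous frequency rises (or falls) linearly from `f_start` to `f_end`
#' over the duration; the phase is the integral of the instantaneous
#' frequency. With `f_start == f_end` this reduces to [make_tone()].
#'
#' @param f_start,f_end Sweep endpoints in Hz, both in `(0, sample_rate/2)`.
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate in Hz.
#' @param amplitude Peak amplitude.
#' @return A mono [audio_signal].
#' @export
make_chirp <- function(f_start, f_end, duration, sample_rate, amplitude = 1) {
  for (f in c(f_start, f_end))
    if (f <= 0 || f >= sample_rate / 2)
      stop(sprintf("configuration error: frequency %g Hz outside (0, Nyquist = %g Hz)",
                   f, sample_rate / 2))
  if (duration <= 0) stop("configuration error: duration must be > 0")
  if (amplitude <= 0) stop("configuration error: amplitude must be > 0")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  phase <- 2 * pi * (f_start * t + (f_end - f_start) * t^2 / (2 * duration))
  audio_signal(amplitude * sin(phase), sample_rate)
}

#' Specification of one synthetic syllable
#'
#' @param f0 Fundamental in Hz: a single value for a constant tone or a
#'   `c(start, end)` pair for a linear sweep.
#' @param duration Syllable duration in seconds.
#' @param amplitude Peak amplitude of the fundamental.
#' @param harmonics Optional list of `c(multiple, relative_amplitude)` pairs;
#'   multiples must be integers >= 2. A relative amplitude above 1 makes the
#'   harmonic dominate the fundamental (useful to exercise the tracker's
#'   documented harmonic limitation).
#' @param onset_ramp Raised-cosine fade in/out length in seconds; avoids the
#'   spectral splatter a hard edge would leak across the silence gate. Must
#'   satisfy `2 * onset_ramp <= duration`.
#' @return An object of class `syllable_spec`.
#' @export
syllable_spec <- function(f0, duration, amplitude = 1, harmonics = NULL,
                          onset_ramp = 0.005) {
  if (length(f0) == 1L) f0 <- c(f0, f0)
  if (length(f0) != 2L || any(f0 <= 0))
    stop("configuration error: f0 must be one positive value or a start/end pair")
  if (duration <= 0) stop("configuration error: duration must be > 0")
  if (amplitude <= 0) stop("configuration error: amplitude must be > 0")
  if (onset_ramp < 0 || 2 * onset_ramp > duration)
    stop("configuration error: need 2 * onset_ramp <= duration")
  for (h in harmonics) {
    if (length(h) != 2L || h[1L] < 2 || h[1L] != round(h[1L]) || h[2L] < 0)
      stop("configuration error: each harmonic must be c(integer multiple >= 2, relative amplitude >= 0)")
  }
  structure(list(f0 = f0, duration = duration, amplitude = amplitude,
                 harmonics = harmonics, onset_ramp = onset_ramp),
            class = "syllable_spec")
}

render_syllable <- function(spec, sample_rate) {
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  f0 <- spec$f0
  top <- max(f0) * max(1, vapply(spec$harmonics, `[`, numeric(1), 1L), 1)
  if (top >= sample_rate / 2)
    stop(sprintf("configuration error: partial at %g Hz reaches Nyquist (%g Hz)",
                 top, sample_rate / 2))
  phase <- 2 * pi * (f0[1L] * t + (f0[2L] - f0[1L]) * t^2 / (2 * spec$duration))
  wave <- sin(phase)
  for (h in spec$harmonics) wave <- wave + h[2L] * sin(h[1L] * phase)
  ramp_n <- round(spec$onset_ramp * sample_rate)
  if (ramp_n > 0L) {
    fade <- 0.5 - 0.5 * cos(pi * (seq_len(ramp_n) - 1L) / ramp_n)
    wave[seq_len(ramp_n)] <- wave[seq_len(ramp_n)] * fade
    wave[n - ramp_n + seq_len(ramp_n)] <- wave[n - ramp_n + seq_len(ramp_n)] * rev(fade)
  }
  spec$amplitude * wave
}

#' Generate a syllable train with ground truth
#'
#' Concatenates `silence(gap) + syllable + silence(gap) + ...` ending with a
#' final gap, optionally adding zero-mean white Gaussian noise of the given
#' RMS over the whole signal. With `noise_rms = 0` the gaps are exactly zero,
#' enabling exact silence-gating tests. The generator is deterministic given
#' its arguments and seed, and never touches the global random state.
#'
#' @param specs List of [syllable_spec()] objects (non-empty).
#' @param gap Silence length between (and around) syllables, seconds, >= 0.
#' @param sample_rate Sample rate in Hz.
#' @param noise_rms RMS of the additive white Gaussian background noise (>= 0).
#' @param seed Integer seed for the noise; required when `noise_rms > 0`.
#' @return List with `signal` (an [audio_signal]) and `truth`, a data.frame
#'   with one row per syllable: `onset`, `offset` (seconds), `f0_start`,
#'   `f0_end` (Hz). The f0 trajectory of syllable `i` at time `t` is
#'   `f0_start + (f0_end - f0_start) * (t - onset) / (offset - onset)`.
#' @examples
#' tr <- make_syllable_train(list(syllable_spec(2000, 0.1)), gap = 0.15,
#'                           sample_rate = 44100)
#' tr$truth
#' @export
make_syllable_train <- function(specs, gap, sample_rate, noise_rms = 0,
                                seed = NULL) {
  if (length(specs) == 0L) stop("configuration error: specs must be non-empty")
  if (gap < 0) stop("configuration error: gap must be >= 0")
  if (noise_rms < 0) stop("configuration error: noise_rms must be >= 0")
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "syllable_spec")) stop("configuration error: specs must be syllable_spec objects")
    s
  })

  gap_n <- round(gap * sample_rate)
  pieces <- list()
  onset <- numeric(length(specs))
  offset <- numeric(length(specs))
  pos <- 0L
  for (i in seq_along(specs)) {
    pieces[[length(pieces) + 1L]] <- numeric(gap_n)
    pos <- pos + gap_n
    syl <- render_syllable(specs[[i]], sample_rate)
    onset[i] <- pos / sample_rate
    offset[i] <- (pos + length(syl)) / sample_rate
    pieces[[length(pieces) + 1L]] <- syl
    pos <- pos + length(syl)
  }
  pieces[[length(pieces) + 1L]] <- numeric(gap_n)
  samples <- unlist(pieces, use.names = FALSE)

  if (noise_rms > 0) {
    if (is.null(seed)) stop("configuration error: a seed is required when noise_rms > 0")
    samples <- samples + with_preserved_rng(seed, stats::rnorm(length(samples),
                                                               sd = noise_rms))
  }

  list(signal = audio_signal(samples, sample_rate),
       truth = data.frame(onset = onset, offset = offset,
                          f0_start = vapply(specs, function(s) s$f0[1L], numeric(1)),
                          f0_end = vapply(specs, function(s) s$f0[2L], numeric(1))))
}

# Run expr under a fixed seed without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
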