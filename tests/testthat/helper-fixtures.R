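# Shared fixtures and independent oracles. Everything is generated in code;
# no binary files ship with the package.

# Exhaustive two-loop maximum scan; the independent oracle for
# peak_frequency_per_bin (lowest-frequency tie break).
argmax_oracle <- function(freqs, power) {
  nf <- nrow(power); nt <- ncol(power)
  best_f <- numeric(nt); best_p <- numeric(nt)
  for (k in seq_len(nt)) {
    bi <- 1L
    for (i in seq_len(nf)) if (power[i, k] > power[bi, k]) bi <- i
    best_f[k] <- freqs[bi]
    best_p[k] <- power[bi, k]
  }
  list(frequency = best_f, power = best_p)
}

# Minimal spectrogram object with arbitrary power, for unit tests that do not
# need a real signal behind the grid.
fake_grid <- function(power, freqs = seq_len(nrow(power)) * 100 - 100,
                      sr = 8000, window = 256L, hop = 128L) {
  structure(list(
    times = ((seq_len(ncol(power)) - 1L) * hop + window / 2) / sr,
    freqs = freqs, power = power,
    meta = list(window = window, hop = hop, overlap = window - hop,
                window_function = "hann", sample_rate = sr)
  ), class = "spectrogram")
}

# The canonical noiseless 5-syllable canary-like train used across tests:
# 100 ms bursts at 1..5 kHz separated by 150 ms of true silence.
canary_train <- function(sample_rate = 44100, noise_rms = 0, seed = NULL,
                         harmonics = NULL) {
  specs <- lapply(c(1000, 2000, 3000, 4000, 5000), function(f)
    syllable_spec(f, 0.1, amplitude = 0.8, harmonics = harmonics))
  make_syllable_train(specs, gap = 0.15, sample_rate = sample_rate,
                      noise_rms = noise_rms, seed = seed)
}

# Window extents [start, end) in seconds for each time bin of a track/grid.
bin_extents <- function(obj) {
  meta <- if (inherits(obj, "spectrogram")) obj$meta else obj$grid$meta
  starts <- (seq_along(obj$times) - 1L) * meta$hop / meta$sample_rate
  list(start = starts, end = starts + meta$window / meta$sample_rate)
}

# Classify each bin of a track of a syllable train: fully inside a burst,
# fully inside a gap, or straddling an edge.
classify_bins <- function(track, truth) {
  ext <- bin_extents(track)
  in_burst <- rep(FALSE, length(ext$start))
  in_gap <- rep(TRUE, length(ext$start))
  for (i in seq_len(nrow(truth))) {
    on <- truth$onset[i]; off <- truth$offset[i]
    in_burst <- in_burst | (ext$start >= on & ext$end <= off)
    in_gap <- in_gap & !(ext$end > on & ext$start < off)
  }
  list(burst = in_burst, gap = in_gap)
}

# Hand-assembled 16-bit PCM mono WAV byte stream: an oracle for read_wav that
# does not depend on write_wav.
manual_wav_bytes <- function(values_int16, sample_rate = 8000L, n_channels = 1L) {
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  data <- writeBin(as.integer(values_int16), raw(), size = 2L, endian = "little")
  c(charToRaw("RIFF"), u32(36L + length(data)), charToRaw("WAVE"),
    charToRaw("fmt "), u32(16L), u16(1L), u16(n_channels), u32(sample_rate),
    u32(sample_rate * n_channels * 2L), u16(n_channels * 2L), u16(16L),
    charToRaw("data"), u32(length(data)), data)
}

# Self-contained analytic signal + phase unwrap for instantaneous-frequency
# checks, written independently of the package internals.
analytic_signal_for_test <- function(x) {
  n <- length(x)
  h <- numeric(n)
  half <- n %/% 2
  if (n %% 2 == 0) { h[c(1, half + 1)] <- 1; h[2:half] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) %/% 2)] <- 2 }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

unwrap_for_test <- function(phase) {
  d <- diff(phase)
  jumps <- round(d / (2 * pi))
  phase - c(0, cumsum(jumps)) * 2 * pi
}
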