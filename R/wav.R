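# RIFF/WAVE reader and writer. Supports linear PCM (8/16/24/32-bit) and IEEE
# float (32/64-bit), including WAVE_FORMAT_EXTENSIBLE headers. Integer samples
# are normalized by the encoding's maximum magnitude (2^(bits-1)) so a
# full-scale waveform maps to [-1, 1] regardless of bit depth.

WAVE_FORMAT_PCM        <- 1L
WAVE_FORMAT_IEEE_FLOAT <- 3L
WAVE_FORMAT_EXTENSIBLE <- 65534L

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file into an [audio_signal]. Integer PCM encodings
#' (8, 16, 24, 32 bit) are rescaled to \[-1, 1\] by dividing by the type's
#' maximum magnitude (e.g. 32768 for 16-bit); IEEE float samples are taken
#' as-is. The channel layout is preserved; use [to_mono()] to collapse it.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal]; stereo files yield a frames-by-2 sample matrix.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop(sprintf("unsupported format: not a RIFF file: %s", path))
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # chunk size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("unsupported format: not a WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- parse_fmt_chunk(fmt_raw)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding to even size
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("unsupported format: missing fmt chunk")
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("empty input: WAV file contains zero frames")

  samples <- decode_wav_samples(data_raw, fmt)
  n <- length(samples) %/% fmt$n_channels
  if (n < 1L) stop("empty input: WAV file contains zero frames")
  samples <- samples[seq_len(n * fmt$n_channels)]
  if (fmt$n_channels > 1L)
    samples <- matrix(samples, ncol = fmt$n_channels, byrow = TRUE)
  audio_signal(samples, fmt$sample_rate)
}

parse_fmt_chunk <- function(raw) {
  u16 <- function(off) readBin(raw[off + 1:2], "integer", 1L, size = 2L,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[off + 1:4], "integer", 1L, size = 4L,
                               endian = "little")
  format <- u16(0L)
  fmt <- list(format = format, n_channels = u16(2L), sample_rate = u32(4L),
              bits = u16(14L))
  if (format == WAVE_FORMAT_EXTENSIBLE) {
    if (length(raw) < 26L) stop("unsupported format: truncated extensible fmt chunk")
    fmt$format <- u16(24L)  # first two bytes of the subformat GUID
  }
  if (!fmt$format %in% c(WAVE_FORMAT_PCM, WAVE_FORMAT_IEEE_FLOAT))
    stop(sprintf("unsupported format: WAV codec tag %d (only PCM and IEEE float are supported)",
                 fmt$format))
  if (fmt$n_channels < 1L) stop("unsupported format: zero channels")
  fmt
}

decode_wav_samples <- function(raw, fmt) {
  bits <- fmt$bits
  if (fmt$format == WAVE_FORMAT_IEEE_FLOAT) {
    if (!bits %in% c(32L, 64L))
      stop(sprintf("unsupported format: %d-bit float WAV", bits))
    return(readBin(raw, "double", length(raw) %/% (bits / 8L), size = bits / 8L,
                   endian = "little"))
  }
  n <- length(raw) %/% (bits / 8L)
  switch(as.character(bits),
    "8" = (readBin(raw, "integer", n, size = 1L, signed = FALSE) - 128) / 128,
    "16" = readBin(raw, "integer", n, size = 2L, endian = "little") / 32768,
    "24" = {
      b <- as.integer(raw[seq_len(n * 3L)])
      v <- b[seq(1L, by = 3L, length.out = n)] +
           b[seq(2L, by = 3L, length.out = n)] * 256 +
           b[seq(3L, by = 3L, length.out = n)] * 65536
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    "32" = readBin(raw, "integer", n, size = 4L, endian = "little") / 2147483648,
    stop(sprintf("unsupported format: %d-bit PCM WAV", bits))
  )
}

#' Write a WAV file
#'
#' Writes an [audio_signal] as 16-bit PCM (default) or 32-bit IEEE float.
#' For PCM, samples are scaled by 32768, rounded and clipped to the 16-bit
#' range, so a write/read round trip agrees with the original within one
#' quantization step (2^-15).
#'
#' @param x An [audio_signal] (mono or multi-channel).
#' @param path Output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(x, "audio_signal"))
  format <- match.arg(format)
  nch <- n_channels(x)
  samples <- if (is.matrix(x$samples)) as.numeric(t(x$samples)) else x$samples

  bits <- if (format == "pcm16") 16L else 32L
  tag  <- if (format == "pcm16") WAVE_FORMAT_PCM else WAVE_FORMAT_IEEE_FLOAT
  data_size <- length(samples) * (bits %/% 8L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(tag, con, size = 2L, endian = "little")
  writeBin(as.integer(nch), con, size = 2L, endian = "little")
  writeBin(as.integer(x$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(x$sample_rate * nch * bits / 8L), con, size = 4L,
           endian = "little")
  writeBin(as.integer(nch * bits / 8L), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (format == "pcm16") {
    q <- pmin(pmax(round(samples * 32768), -32768), 32767)
    writeBin(as.integer(q), con, size = 2L, endian = "little")
  } else {
    writeBin(samples, con, size = 4L, endian = "little")
  }
  invisible(path)
}
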