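#' @export
print.f0_track <- function(x, ...) {
  nv <- sum(x$voiced)
  cat(sprintf("<f0_track> %d time bins over %.3f s; %d voiced (%.1f%%)\n",
              length(x$times), max(x$times) + x$config$window /
                (2 * x$signal$sample_rate),
              nv, 100 * nv / length(x$times)))
  if (nv > 0)
    cat(sprintf("  f0: median %.1f Hz, range %.1f-%.1f Hz\n",
                stats::median(x$f0_hz[x$voiced]),
                min(x$f0_hz[x$voiced]), max(x$f0_hz[x$voiced])))
  if (length(x$warnings))
    cat(sprintf("  %d configuration warning(s); see $warnings\n",
                length(x$warnings)))
  invisible(x)
}

#' @export
summary.f0_track <- function(object, ...) {
  v <- object$voiced
  out <- list(
    n_bins = length(object$times),
    n_voiced = sum(v),
    voiced_fraction = mean(v),
    time_step_s = if (length(object$times) > 1L)
      object$times[2L] - object$times[1L] else NA_real_,
    bin_width_hz = object$signal$sample_rate / object$config$window,
    f0_summary = if (any(v)) summary(object$f0_hz[v]) else NULL,
    threshold_value = object$threshold_value,
    warnings = object$warnings
  )
  class(out) <- "summary.f0_track"
  out
}

#' @export
print.summary.f0_track <- function(x, ...) {
  cat(sprintf("f0 track: %d bins (step %.4f s), %d voiced (%.1f%%)\n",
              x$n_bins, x$time_step_s, x$n_voiced, 100 * x$voiced_fraction))
  cat(sprintf("frequency bin width: %.2f Hz; envelope gate: %.4g\n",
              x$bin_width_hz, x$threshold_value))
  if (!is.null(x$f0_summary)) {
    cat("voiced f0 (Hz):\n")
    print(x$f0_summary)
  } else cat("no voiced bins\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' @export
as.data.frame.f0_track <- function(x, ...) {
  data.frame(time_s = x$times, f0_hz = x$f0_hz, voiced = x$voiced,
             peak_power = x$peak_power, envelope_level = x$bin_levels)
}

#' Plot an f0 track
#'
#' Four stacked panels: the waveform, the spectrogram (dB scale), the f0
#' estimates overlaid on the spectrogram, and f0 versus time on its own axis.
#'
#' @param x An `f0_track`.
#' @param ... Unused.
#' @return Invisibly, a list of the data plotted in each panel.
#' @export
plot.f0_track <- function(x, ...) {
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(op))
  sig <- x$signal
  tt <- (seq_len(n_frames(sig)) - 1L) / sig$sample_rate
  graphics::plot(tt, sig$samples, type = "l", xlab = "", ylab = "amplitude",
                 col = "grey30")
  draw_spectrogram(x$grid)
  draw_spectrogram(x$grid)
  graphics::points(x$times, x$f0_hz, pch = 16, cex = 0.4, col = "red")
  graphics::plot(x$times, x$f0_hz, pch = 16, cex = 0.5, col = "red",
                 xlim = range(tt), ylim = range(x$grid$freqs),
                 xlab = "time (s)", ylab = "f0 (Hz)")
  invisible(list(waveform = list(time = tt, amplitude = sig$samples),
                 f0 = list(time = x$times, f0_hz = x$f0_hz)))
}

draw_spectrogram <- function(grid) {
  db <- 10 * log10(grid$power + 1e-12)
  graphics::image(grid$times, grid$freqs, t(db), col = grDevices::hcl.colors(64),
                  xlab = "", ylab = "frequency (Hz)", useRaster = TRUE)
}

#' Write an f0 track as a plain-text table
#'
#' One row per time bin: time in seconds and f0 in Hz, tab-separated, with a
#' single `#`-prefixed header naming the columns and units. Silent bins carry
#' the literal token `nan`, or are omitted entirely with `drop_silent = TRUE`.
#' Values are printed to 6 significant digits.
#'
#' @param track An `f0_track`.
#' @param path Output path.
#' @param drop_silent Omit silent bins instead of writing `nan` rows.
#' @return `path`, invisibly.
#' @seealso [read_track_table()]
#' @export
write_track_table <- function(track, path, drop_silent = FALSE) {
  stopifnot(inherits(track, "f0_track"))
  keep <- if (drop_silent) track$voiced else rep(TRUE, length(track$times))
  f0 <- ifelse(is.nan(track$f0_hz[keep]), "nan",
               sprintf("%.6g", track$f0_hz[keep]))
  lines <- c("# time_s\tf0_hz",
             paste(sprintf("%.6g", track$times[keep]), f0, sep = "\t"))
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("I/O error writing %s: %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' Read a track table written by [write_track_table()]
#'
#' @param path Path to the table.
#' @return A data.frame with `time_s` and `f0_hz` (`NaN` for silent rows).
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: file not found: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          col.names = c("time_s", "f0_hz"),
                          na.strings = "nan", colClasses = "numeric")
  df$f0_hz[is.na(df$f0_hz)] <- NaN
  df
}

#' Render the diagnostic figure for a track
#'
#' Writes the four-panel plot of [plot.f0_track()] (waveform, spectrogram,
#' overlay, f0 vs time) to a raster file. The format follows the file
#' extension: `.png` (default) or `.jpg`/`.jpeg`.
#'
#' @param signal The [audio_signal] the track came from (mono).
#' @param grid The band-restricted `spectrogram`.
#' @param track The `f0_track`; must share `grid`'s time bins.
#' @param path Output path ending in `.png`, `.jpg` or `.jpeg`.
#' @param width,height,res Device geometry passed to the raster device.
#' @return Invisibly, the plotted data (see [plot.f0_track()]).
#' @export
render_track_figure <- function(signal, grid, track, path,
                                width = 1200, height = 900, res = 120) {
  stopifnot(inherits(signal, "audio_signal"), inherits(grid, "spectrogram"),
            inherits(track, "f0_track"))
  if (length(grid$times) != length(track$times) ||
      max(abs(grid$times - track$times)) > 1e-9)
    stop("consistency error: spectrogram and track have different time bins")
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                jpg = , jpeg = function(...) grDevices::jpeg(..., quality = 90),
                grDevices::png)
  dev(filename = path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot_track <- track
  plot_track$signal <- to_mono(signal, track$config$channel_policy)
  plot_track$grid <- grid
  invisible(plot(plot_track))
}
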