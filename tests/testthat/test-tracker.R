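test_that("peak_frequency_per_bin picks the maximum and breaks ties downward", {
  g <- fake_grid(matrix(c(0, 0, 7, 0), ncol = 1), freqs = c(0, 100, 200, 300))
  p <- peak_frequency_per_bin(g)
  expect_equal(p$frequency, 200)
  expect_equal(p$power, 7)

  zero <- fake_grid(matrix(0, 4, 3), freqs = c(50, 100, 200, 300))
  pz <- peak_frequency_per_bin(zero)
  expect_equal(pz$frequency, rep(50, 3))   # tie-break toward lowest frequency
  expect_equal(pz$power, rep(0, 3))

  tie <- fake_grid(matrix(c(1, 5, 5, 0), ncol = 1), freqs = c(0, 100, 200, 300))
  expect_equal(peak_frequency_per_bin(tie)$frequency, 100)
})

test_that("peak picking equals the exhaustive scan on random grids", {
  set.seed(41)
  for (i in 1:50) {
    power <- matrix(stats::rexp(64 * 40), 64, 40)
    freqs <- seq(800, by = 43, length.out = 64)
    g <- fake_grid(power, freqs = freqs)
    got <- peak_frequency_per_bin(g)
    expect_identical(got, argmax_oracle(freqs, power))
  }
})

test_that("a steady tone is tracked within half a bin in every voiced bin", {
  trk <- track_f0(make_tone(2000, 2, 44100, 0.8))
  expect_true(all(trk$voiced))
  bin_width <- 44100 / 1024
  expect_true(all(abs(trk$f0_hz - 2000) <= bin_width / 2))
  expect_equal(length(trk$times), floor((2 * 44100 - 1024) / 512) + 1)
})

test_that("digital silence yields no voiced bins and all-NaN f0", {
  trk <- track_f0(audio_signal(rep(0, 2 * 44100), 44100))
  expect_equal(sum(trk$voiced), 0L)
  expect_true(all(is.nan(trk$f0_hz)))
})

test_that("f0 is NaN exactly where a bin is silent", {
  trk <- track_f0(canary_train()$signal)
  expect_identical(is.nan(trk$f0_hz), !trk$voiced)
  expect_length(trk$f0_hz, length(trk$times))
  expect_length(trk$peak_power, length(trk$times))
})

test_that("syllable trains are gated and tracked per burst", {
  train <- canary_train()
  trk <- track_f0(train$signal)
  bins <- classify_bins(trk, train$truth)
  expect_true(all(trk$voiced[bins$burst]))
  expect_true(all(!trk$voiced[bins$gap]))

  ext <- bin_extents(trk)
  bin_width <- 44100 / 1024
  for (i in seq_len(nrow(train$truth))) {
    sel <- trk$voiced & ext$start >= train$truth$onset[i] &
      ext$end <= train$truth$offset[i]
    expect_lte(abs(stats::median(trk$f0_hz[sel]) - train$truth$f0_start[i]),
               bin_width)
  }
})

test_that("a linear chirp gives a near-monotone track through the midpoint", {
  trk <- track_f0(make_chirp(1000, 5000, 2, 44100, 0.8))
  v <- trk$f0_hz[trk$voiced]
  bin_width <- 44100 / 1024
  expect_true(all(diff(v) >= -bin_width))
  mid <- v[which.min(abs(trk$times[trk$voiced] - 1))]
  expect_lte(abs(mid - 3000), bin_width)
})

test_that("voiced f0 stays inside any configured band", {
  set.seed(42)
  for (i in 1:8) {
    f_min <- stats::runif(1, 300, 3000)
    f_max <- f_min + stats::runif(1, 500, 4000)
    f <- stats::runif(1, f_min + 50, f_max - 50)
    cfg <- tracker_config(f_min = f_min, f_max = f_max)
    trk <- track_f0(make_tone(f, 0.5, 44100, 0.8), cfg)
    expect_true(all(trk$f0_hz[trk$voiced] >= f_min))
    expect_true(all(trk$f0_hz[trk$voiced] <= f_max))
    expect_lte(max(abs(trk$f0_hz[trk$voiced] - f)), 44100 / 1024)
  }
})

test_that("a dominant in-band harmonic is reported, a weak one is not", {
  weak <- canary_train(harmonics = list(c(2, 0.4)))
  trk_w <- track_f0(weak$signal, tracker_config(f_min = 800, f_max = 12000))
  ext <- bin_extents(trk_w)
  sel <- trk_w$voiced & ext$start >= weak$truth$onset[1] &
    ext$end <= weak$truth$offset[1]
  expect_lte(abs(stats::median(trk_w$f0_hz[sel]) - 1000), 44100 / 1024)

  strong <- canary_train(harmonics = list(c(2, 1.5)))
  trk_s <- track_f0(strong$signal, tracker_config(f_min = 800, f_max = 12000))
  sel <- trk_s$voiced & ext$start >= strong$truth$onset[1] &
    ext$end <= strong$truth$offset[1]
  expect_lte(abs(stats::median(trk_s$f0_hz[sel]) - 2000), 44100 / 1024)
})

test_that("amplitude scaling changes neither f0 nor the relative-mode gate", {
  train <- canary_train()
  base <- track_f0(train$signal)
  for (c in c(0.25, 3)) {
    scaled <- audio_signal(c * train$signal$samples, 44100)
    trk <- track_f0(scaled)
    expect_identical(trk$voiced, base$voiced)
    expect_equal(trk$f0_hz, base$f0_hz)
  }
})

test_that("validate_config warns on soft problems without erroring", {
  expect_length(validate_config(tracker_config(), 44100), 0L)

  slow <- validate_config(tracker_config(window = 2048, overlap = 512), 44100)
  expect_match(slow, "window duration", all = FALSE)

  nyq <- validate_config(tracker_config(f_max = 30000), 44100)
  expect_match(nyq, "Nyquist", all = FALSE)

  coarse <- validate_config(tracker_config(window = 64, overlap = 0,
                                           f_min = 800, f_max = 2000), 44100)
  expect_match(coarse, "coarse", all = FALSE)

  expect_warning(track_f0(make_tone(2000, 0.3, 44100),
                          tracker_config(window = 2048, overlap = 512)),
                 "window duration")
})

test_that("tracker_config rejects hard invariant violations", {
  expect_error(tracker_config(overlap = 1024), "overlap")
  expect_error(tracker_config(f_min = 5000, f_max = 1000), "f_min < f_max")
  expect_error(tracker_config(threshold = 1.5), "\\[0, 1\\]")
  expect_error(tracker_config(smooth_ms = -1), "smooth_ms")
  expect_error(tracker_config(window_function = "kaiser"), "arg")
})

test_that("f_max beyond Nyquist is clipped rather than fatal", {
  trk <- suppressWarnings(track_f0(make_tone(2000, 0.5, 8000, 0.8),
                                   tracker_config(f_min = 800, f_max = 30000,
                                                  window = 256, overlap = 128)))
  expect_true(all(trk$f0_hz[trk$voiced] <= 4000))
  expect_lte(max(abs(trk$f0_hz[trk$voiced] - 2000)), 8000 / 256)
})

test_that("track objects print, summarize and convert to data frames", {
  trk <- track_f0(canary_train()$signal)
  expect_output(print(trk), "f0_track")
  s <- summary(trk)
  expect_s3_class(s, "summary.f0_track")
  expect_equal(s$n_voiced, sum(trk$voiced))
  expect_output(print(s), "voiced")
  df <- as.data.frame(trk)
  expect_equal(nrow(df), length(trk$times))
  expect_named(df, c("time_s", "f0_hz", "voiced", "peak_power", "envelope_level"))
})
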