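Package: f0tracker
Title: Fundamental-Frequency Tracking for Tonal Animal Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frequency-domain fundamental-frequency (f0) estimation for tonal
    animal vocalizations such as canary song. A short-time Fourier spectrogram
    is computed over overlapping windowed segments, restricted to a frequency
    band of interest, and the maximum-intensity frequency of each time bin is
    taken as the f0 estimate; an amplitude-envelope threshold gates out silent
    or noisy bins. Includes WAV input/output, a synthetic canary-like signal
    generator with known ground truth for testing, table and figure output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    tools,
    optparse
Suggests:
    signal,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
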