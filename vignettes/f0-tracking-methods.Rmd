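---
title: "Frequency-domain f0 tracking for tonal vocalizations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain f0 tracking for tonal vocalizations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f0tracker)
```

## The estimation problem

The fundamental frequency f0 of a periodic sound is the lowest partial to
which the other partials relate harmonically. For *tonal* vocalizations —
sounds dominated by a single, possibly modulated frequency component, the
regime canary song mostly lives in — nearly all of the signal's energy sits
at f0, so the frequency of the most intense spectrogram bin *is* the f0
estimate. `f0tracker` implements exactly that estimator, plus the two
ingredients that make it usable on real recordings: a frequency-band
restriction and an amplitude-envelope silence gate.

For each time bin $t_k$ of a short-time spectrogram $P(f, t_k)$:

$$\hat f_0(t_k) \;=\; \arg\max_{f \in [f_\min,\, f_\max]} P(f, t_k),
\qquad\text{kept only where } E(t_k) \ge T,$$

where $E$ is the amplitude envelope reduced to one value per bin and $T$ the
silence threshold. Bins failing the gate carry `NaN`, not 0 Hz — 0 Hz is a
legal spectrogram frequency and would corrupt downstream statistics.

## Model assumptions

* **Tonality.** The estimator assumes the fundamental is the most intense
  in-band component. When a harmonic carries more power inside the band, the
  tracker reports the harmonic. This is a documented limitation, not a bug:
  octave correction is out of scope, and the band filter (`f_min`, `f_max`)
  is the only mitigation. The test suite pins this behavior with a
  regression: a syllable with a second harmonic at 0.4 relative amplitude
  tracks at f0, at 1.5 it tracks at 2·f0.
* **Additivity of silence.** The envelope gate assumes silent stretches are
  quieter than song by at least the threshold factor. Diffuse broadband
  noise raises the floor; the relative threshold (fraction of the
  recording's peak envelope) tolerates gain differences between recordings
  but not noise that rivals the song itself.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window` | 1024 | samples | 23.2 ms at 44.1 kHz: below the 33 ms syllabic bound (below), above ~10 ms so the 43 Hz bin width stays useful |
| `overlap` | 512 | samples | 50%: dense time sampling while keeping segments largely independent (no Welch-style averaging is ever applied) |
| `window_function` | `"hann"` | — | standard low-leakage taper; peak picking is insensitive to the exact choice |
| `f_min`, `f_max` | 800, 8000 | Hz | the canary singing range |
| `threshold` | 0.05 | fraction of peak envelope | robust across recording gains; an absolute mode exists for calibrated pipelines |
| `smooth_ms` | 5 | ms | envelope moving-average width: long enough to erase the carrier ripple of an 800 Hz fundamental, short next to any syllable |
| `channel_policy` | `"average"` | — | stereo field recordings carry the same song in both channels |
| `max_syllabic_rate` | 30 | Hz | validation only (below) |

**The time-resolution bound.** Canaries sing 3–30 syllables per second, so
an analysis window must be shorter than 1/30 s ≈ 33 ms to keep adjacent
syllables in separate bins; `time_resolution_bound()` exposes the
reciprocal, and `validate_config()` *warns* (never errors) when
`window / sample_rate` reaches it — window choice is a genuine user
compromise between time and frequency resolution, so the tracker refuses to
make it fatal. The same validation warns when `f_max` exceeds Nyquist
(clipped) and when the bin width is coarser than a quarter of the band.

**Accuracy contract.** No peak interpolation is performed: the estimate is a
raw grid frequency, so the guarantee is ±1 bin width
(`sample_rate / window`), and for a steady tone typically ±half a bin. Ties
in intensity break toward the *lowest* frequency, biasing toward the
fundamental.

## Numerical choices

* **Spectrogram.** Segments start at sample 0 and advance by
  `window − overlap`; trailing samples that do not fill a window are
  discarded, giving `floor((n − window)/hop) + 1` columns with bin-center
  times `(k·hop + window/2)/sample_rate`. The FFT length equals the window
  (no zero padding), and power is the raw squared magnitude of the
  non-negative frequencies. Power is kept *linear*: the per-bin argmax is
  invariant under any monotone rescaling, so dB conversion is cosmetic and
  happens only in plots. A unit test checks each column against
  `signal::specgram` and against Parseval's identity.
* **Envelope.** Magnitude of the analytic signal (FFT method: zero negative
  frequencies, double positive ones, inverse FFT), then a centered moving
  average of `round(smooth_ms·sr/1000)` samples with edge replication. The
  envelope definition in the bioacoustics literature varies (rectification
  vs analytic signal, filter types); the smoothing width is configurable so
  other definitions can be approximated.
* **Per-bin envelope reduction.** The *maximum* over the bin's window extent
  `[k·hop, k·hop + window)`, not the mean: a bin containing any part of a
  syllable onset should count as sound.
* **Gate comparison** is `>=`, so threshold-attaining bins are voiced —
  a deterministic tie rule.
* **Degenerate inputs.** An all-zero recording has zero peak envelope; the
  relative gate would then be vacuously true, so that case is explicitly
  all-silent. All-zero spectrogram columns argmax to the lowest in-band
  frequency and are subsequently gated off.
* **WAV normalization.** Integer PCM is divided by the type's maximum
  magnitude (32768 for 16-bit), keeping envelope thresholds comparable
  across encodings; writing scales by 32768 with clipping at 32767, so a
  write/read round trip stays within one quantization step (2⁻¹⁵).

## The synthetic-signal generator

Real canary recordings are not distributable with the package, so all tests
run on synthesized fixtures that emulate the relevant features of the song:
pure tones and linear sweeps in 800 Hz–8 kHz, syllable trains (default five
100 ms syllables at 1–5 kHz separated by 150 ms silences, i.e. a 4 Hz
syllabic rate with ~23% duty cycle at typical canary frequencies), optional
harmonic partials, raised-cosine onset/offset ramps (5 ms, avoiding the
spectral splatter a hard edge would leak across the gate), and additive
white Gaussian background noise from an explicit seed that never touches the
global RNG.

What the generator does *not* emulate — and hence what passing tests cannot
show: biomechanically realistic syllable shapes (syrinx dynamics, amplitude
modulation), reverberation, colored or non-stationary noise, and overlapping
singers. Results on such recordings depend on the envelope gate's margin and
should be inspected via `render_track_figure()`.

## Problem sizes in the tests

The test and acceptance runs use short fixtures — 0.4–2 s of 44.1 kHz audio,
100 random 64×40 grids for the peak-picking oracle, 20 random tone
frequencies at three window sizes — chosen so the whole suite documents the
estimator's contracts (one-bin tone recovery, exact gating on noiseless
trains, band closure, gain/polarity invariance, serialization round trips)
while running in seconds. The contracts themselves are size-free.

## Known limitations

* Harmonic-dominant sounds track at the harmonic (see above).
* No pitch smoothing, octave correction, or syllable segmentation is
  applied; the output is the raw per-bin track.
* Half-bin accuracy is typical but only one-bin accuracy is guaranteed; for
  finer resolution increase `window` (at the cost of time resolution) rather
  than expecting interpolation.
* The relative threshold is tied to the loudest event in the recording; a
  single clipped transient can raise the gate. Use the absolute mode for
  calibrated pipelines.
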