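---
title: "The two-stage spectral model of sound texture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-stage spectral model of sound texture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundtexture)
```

## The model

Sound textures — rain, wind, fire crackling, applause — are perceived through
time-averaged statistics rather than through the exact temporal arrangement of
acoustic events. `soundtexture` implements a deliberately minimal hypothesis
about which statistics matter: a texture is characterized by exactly two
amplitude spectra.

1. **First stage** — the 1D Fourier amplitude spectrum of the waveform itself
   (the temporal-frequency axis, $F_t$).
2. **Second stage** — the 2D Fourier amplitude spectrum of the *cochlear
   subband envelope matrix*: the waveform is split into 32 channels on the
   ERB-N scale, each channel's Hilbert envelope is sampled at 400 Hz and
   compressed by a power law ($x^{0.3}$, emulating cochlear transduction),
   and the resulting channels-by-time matrix is transformed jointly over time
   (modulation frequency, $F_t$) and channel ($F_{freq}$) axes.

The second spectrum captures how fast each channel's energy fluctuates *and*
how those fluctuations are arranged across frequency channels, i.e. the joint
modulation structure, while discarding all phase — the "where exactly in
time" — of that structure.

The model is tested by metamer synthesis. Two surrogates are generated from
any input:

* **PR** (phase-randomized): preserves only the first-stage spectrum. The
  waveform's DFT phases are replaced by white-noise phases
  (`synthesize_pr()`).
* **le-PR**: preserves both spectra. The original's 2D envelope amplitude
  spectrum is combined with the 2D envelope *phase* spectrum of a PR sound,
  inverted into new subband envelopes, and the PR subbands are remodulated by
  them (`synthesize_lepr()`).

If texture perception is governed by the two spectra, le-PR should sound like
the original while PR — which shares only the long-term spectrum — should
collapse into generic band-passed noise for modulated textures. The package
operationalizes this objectively: on every modulated fixture, le-PR's 2D
envelope-spectrum error against the original is strictly smaller than PR's,
le-PR retains the fixture's known modulation peak, and PR attenuates it by
more than 6 dB (see `tests/testthat/test-acceptance.R`, which computes all of
these).

## The synthesis pipeline

`synthesize_lepr()` performs, in order:

1. Preprocessing: mono mixdown, resampling to 48 kHz, RMS normalization to
   0.1, truncation to a 3 s segment; 600 ms raised-cosine edge tapers are
   applied before every spectral calculation to suppress boundary artifacts.
2. PR generation (white-noise phases on the tapered amplitude spectrum).
3. Cochlear analysis of both the tapered original and the PR sound:
   32 zero-phase frequency-domain filters; Hilbert envelopes; band-limited
   downsampling to 400 Hz; half-wave flooring; compression by 0.3.
4. Imposition: target 2D amplitude from the original's envelope matrix,
   2D phase from the PR's; inverse 2D FFT; imaginary residue (numerically
   ~1e-16) discarded; negative values floored at zero.
5. Reconstruction: each PR subband is divided by its own full-rate Hilbert
   envelope (floored at `envelope_floor_eps`) to expose its fine structure,
   multiplied by the new envelope (decompressed by `^(1/0.3)` and upsampled
   back to the audio rate), refiltered by its channel gain to remove
   out-of-band products of the multiplication, and the channels are summed.

An optional outer loop (`n_outer_iterations > 1`) re-imposes the original's
linear spectrum on the result and repeats from step 3 with the result as the
new phase carrier. The default is a single pass.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `sample_rate_hz` | 48000 | Hz | working audio rate |
| `segment_s` | 3 | s | synthesis segment |
| `taper_s` | 0.6 | s | raised-cosine edge ramps |
| `n_bandpass` | 30 | — | band-pass channels (32 with LP + HP) |
| `f_lo_hz`, `f_hi_hz` | 20, 10000 | Hz | filterbank passband |
| `env_rate_hz` | 400 | Hz | envelope sample rate |
| `compression_exponent` | 0.3 | — | cochlear compression power |
| `target_rms` | 0.1 | — | preprocessing loudness anchor |
| `seed` | 0 | — | RNG seed for the random phases |
| `n_outer_iterations` | 1 | — | outer synthesis passes |
| `envelope_floor_eps` | 1e-8 | — | floor before fine-structure division |

The first eight rows are the model's study conditions; the last three are
implementation choices. `target_rms = 0.1` keeps float WAV output safely
inside $[-1, 1]$ even after synthesis redistributes sample amplitudes (the
precise value only fixes an overall scale — every stage downstream is either
scale-covariant or scale-invariant, which the test suite asserts).
`envelope_floor_eps` guards the fine-structure division in channels that are
essentially silent; any value far below typical envelope magnitudes and far
above denormals behaves identically.

## The filterbank

The 30 band-pass centers are equally spaced on the ERB-number axis
`erb_number(f) = 21.4 log10(4.37 f / 1000 + 1)` between 20 Hz and 10 kHz.
Each gain curve is a half cosine on that axis spanning its two neighboring
centers, so adjacent squared gains sum to one; a low-pass and a high-pass
channel complete the sum below the lowest and above the highest center. We
extend the low-pass to unity below 20 Hz and the high-pass to unity above
10 kHz, making the analysis–synthesis pair transparent for arbitrary signals
(round-trip SNR is at machine precision, asserted at ≥ 40 dB). This
perfect-reconstruction design is what makes step 5 possible; it also fixes an
interpretation of the bandwidth: each channel's 3 dB width is tied to the ERB
spacing of its neighbors rather than to an independent bandwidth parameter.
Filtering is multiplication of the full-length one-sided spectrum — exactly
zero phase, no group delay, filters designed per signal length, no block
processing.

## Numerical choices

* **Envelope operator**: magnitude of the analytic signal (FFT method). It is
  exact for a channel-centered tone (the compression exponent is recovered to
  machine precision as a log-log slope — the acceptance script's check) and
  is the standard reading of "subband energy" in cochlear models.
* **Order of operations**: envelopes are downsampled to 400 Hz first, then
  compressed — the literal pipeline order. Downsampling is brick-wall
  Fourier truncation (no aliasing, no passband ripple); upsampling is its
  exact adjoint (Fourier zero-padding).
* **Rectification**: the inverse 2D transform can produce negative
  "energies"; these have no physical meaning and would break the
  `^(1/0.3)` decompression, so they are floored at zero. The matched-source
  imposition path is unaffected (it is an exact identity, asserted at 1e-9).
* **Random phases** are drawn uniformly on $(-\pi, \pi]$ from a seeded
  generator — the phase distribution of white noise — with DC and Nyquist
  bins kept real and conjugate symmetry enforced, so the output is exactly
  real and bitwise reproducible per seed. The caller's RNG state is saved
  and restored.
* **Degenerate inputs**: all-zero signals are rejected where an operation is
  undefined on them (RMS normalization, round-trip SNR) and propagate as
  zeros where it is defined (filtering, envelopes, spectra).

## What the fixture generators emulate — and what they do not

No natural-sound corpus ships with the package. The generators produce
signals whose two-stage structure is known in closed form, which is what the
tests need:

* `gen_white_noise()` — the unmodulated extreme; flat band-power density.
* `gen_am_noise()` — band-pass noise with sinusoidal amplitude modulation:
  the canonical repetitive texture (sirens, bells, writing); its envelope
  spectrum has a discrete peak at the modulation rate.
* `gen_click_train()` — jittered broadband impulses (crackling-like).
* `gen_multiband_texture()` — different modulation rates in disjoint carrier
  bands, exercising the joint time-by-channel structure that distinguishes
  the 2D envelope spectrum from 32 independent 1D spectra.

Real textures differ in ways these fixtures deliberately avoid: envelope
distributions are heavy-tailed rather than sinusoidal, modulation is
broadband rather than discrete, and cross-channel envelope *phase*
relationships (the cue the model discards) can be perceptually relevant —
e.g. for knocks and other event-like sounds. Passing tests therefore
demonstrate that the machinery preserves and discards exactly what the model
says it should, not that le-PR is a perceptual metamer for every natural
sound; the model itself omits higher-order statistics such as cross-band
correlations by design.

## Known limitations and behavior worth knowing

**Envelope bandwidth ceiling.** The 400 Hz envelope rate caps recoverable
modulation at 200 Hz. High channels are wider than that, so even the
degenerate identity path (feeding the original as its own phase carrier)
reconstructs with an error set by the fixture's occupied-channel bandwidth:
we measure ≈ 54 dB SNR for a 200–800 Hz carrier, ≈ 45 dB for 300–1200 Hz,
≈ 30 dB for 500–2000 Hz. The identity-path test uses the 300–1200 Hz
fixture, whose occupied channels fit under the ceiling; this is a property
of the model's sampling choice, not of the implementation.

**First-stage drift of le-PR.** Imposing the 2D amplitude with random phase
redistributes envelope-fluctuation power across channels (the cross-channel
DFT magnitudes are preserved but their phases are scrambled), and the convex
`^(1/0.3)` decompression turns that into band-power changes of a few dB
(worst band ≤ 6 dB on the standard fixtures, asserted in the tests). PR, by
construction, preserves the first stage to 1e-9. Users who need the first
stage exact can apply `impose_linear_spectrum()` to the le-PR output (exact,
idempotent) or iterate via `n_outer_iterations`, which reduces the drift
only gradually because each pass ends with an envelope imposition.

**Sub-2 Hz modulation readout.** On a 3 s segment the 600 ms tapers and slow
envelope drift dominate modulation bins below about 2 Hz, and in le-PR the
original's taper-skirt energy legitimately reappears as slow random drift.
`dominant_modulation_hz()` therefore reports the strongest component at or
above 2 Hz by default; the floor is an argument, not a constant.

**Sparse sounds.** For click trains, phase randomization of the envelope
spectrum spreads sparse spikes into dense moderate values; after
decompression this lowers the overall level substantially (the le-PR of a
click train has roughly a tenth of the original's RMS). Level-normalized
comparisons are the meaningful ones for such material — the metrics offer
`normalize = TRUE` for exactly this reason.

**Problem sizes in the tests.** Unit tests run a reduced geometry (24 kHz,
1.5 s segments, 300 ms tapers) that keeps every property intact — the
passband still ends at 10 kHz below Nyquist, and envelope frames number 600.
The acceptance tests and the acceptance script run the full study conditions
(48 kHz, 3 s, 600 ms tapers, 1200 envelope frames, 19 200 unique 2D
amplitude points).

## Reproducibility

Every stochastic step flows from a single integer seed: the PR phases from
`cfg$seed`, each fixture generator from its own `seed` argument (the
multiband generator derives component seeds as `seed + i - 1`). Identical
input, configuration, and seed give bitwise-identical PR and le-PR outputs;
the suite asserts this, and the CLI defaults to seed 0 rather than entropy.
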