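---
title: "Methods: simulation and analysis of embryonic PPG signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of embryonic PPG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoppg)
```

This vignette documents the models, parameter choices and numerical
decisions behind `embryoppg`. The package implements, end to end, an
optical viability screen for incubated chicken embryos: a modulated light
source illuminates the egg, vascular pulsations of a viable embryo
modulate the transmitted intensity, and the demodulated envelope is
analysed in the time–frequency domain to decide viable vs non-viable.

## Signal model

The digitized photodetector signal is modelled as

$$X[n] = (A_0 + e[n])\,\sin\!\left(2\pi \tfrac{f}{f_s} n + \varphi\right) + m[n] + w[n],$$

with carrier frequency $f = 2$ kHz, sampling rate $f_s = 96$ kHz (48
samples per carrier cycle), static-attenuation amplitude $A_0$
(`carrier_bias`, default 10 mV), pulsatile envelope $e[n]$, additive
mains tone $m[n]$ (50 Hz, 1 mV) and white sensor noise $w[n]$ (0.5 mV
RMS). All amplitudes are in mV throughout; the optical-to-electrical
calibration factor is fixed at 1.

Three amplitude-domain components ride on the carrier:

* the embryo's envelope — for **viable** profiles a deterministic
  pulse train, fundamental at `pulse_rate` (default 4 Hz, the observed
  embryonic pulse frequency at days 10–14) plus a second harmonic at 25%
  relative amplitude for PPG-like asymmetry, scaled so its peak-to-peak
  equals `pulse_amplitude`; for **non-viable** profiles seeded
  band-limited (0–7 Hz) noise scaled so its peak-to-peak equals
  `nonviable_amplitude` (default 0.4 mV) — dead embryos have no
  deterministic periodic component;
* slow ambient **baseline drift**: three seeded sinusoids below
  `ambient_drift_max_freq` (0.5 Hz) plus a band-limited random walk,
  jointly scaled to `ambient_drift_amplitude` (2 mV) peak. Drift is
  applied in the amplitude domain deliberately: an *additive* near-DC
  term at the raw stage would be annihilated by lock-in demodulation,
  whereas observed envelopes do carry drift — so the physical mechanism
  must be slow modulation of the received light level. The random walk
  is synthesized in the Fourier domain with $1/f$ weighting and strictly
  zero content above `ambient_drift_max_freq`; a raw cumulative-sum walk
  would leak broadband power into the pulse band, which contradicts the
  parameter's meaning and would make "baseline drift" partly
  irremovable by any baseline filter;
* **arrangement-dependent noise**. Three source–detector geometries are
  emulated as presets reproducing only their reported signatures:
  mean viable amplitudes of 1.0 / 4.5 / 3.7 mV for arrangements a/b/c,
  broadband 0–15 Hz envelope noise largest for (b), and for (c) a
  well-defined high-frequency component (realized as a 12 Hz tone,
  0.15 mV RMS) that the 7 Hz low-pass removes. The low-band RMS values
  (a: 0.02, b: 0.5, c: 0.04 mV) are the package's own choices respecting
  the reported qualitative ordering; no optics is computed.

Overmodulation is rejected: the instantaneous carrier amplitude
$A_0 + e[n]$ must stay positive for every generated trace.

### Multi-day trend

Across incubation days 10–14 the pulse amplitude follows a unimodal
raised-cosine trend, maximal at the embryo's `peak_day` (default 12 —
cardiovascular maturation peaks there, after which the growing embryo
attenuates the optical path), strictly increasing before and decreasing
after within ±3 days, with a floor of 0.35 of the peak amplitude. The
floor keeps early (day-10) and late signals weak *but still pulsatile*,
matching the observation that acquisition succeeds on every day even
though day-10 intensity is low. Monitoring batches draw per-embryo peak
days in 11–13.

### Determinism

Every stochastic component is seeded. Batch generators derive per-embryo
sub-seeds deterministically from the master seed, so identical calls
reproduce bitwise-identical traces.

### What the generator does not emulate

Real beat-to-beat heart-rate variability, movement artifacts, waveform
morphology changes with development, optical path physics, electronics
nonlinearity and inter-egg shell variability are all absent. Passing
tests therefore demonstrate the correctness and calibration of the
*signal chain* under the stated signal model — not field performance on
real eggs, for which the amplitude and noise levels here are a stylized
summary.

## Lock-in demodulation

References $S[n] = \sin(2\pi f/f_s\, n)$ and $C[n] = \cos(2\pi f/f_s\,n)$
are precomputed once. Windows are restricted to whole carrier cycles so
$\sum S^2 = \sum C^2 = N/2$ and $\sum SC = 0$ hold exactly; non-integer
samples-per-cycle configurations are rejected rather than approximated,
keeping the scaling identities exact. With

$$I = \sum_{n=0}^{N-1} X[n] S[n], \quad Q = \sum_{n=0}^{N-1} X[n] C[n],
\quad A = \frac{2}{N}\sqrt{I^2+Q^2},$$

a pure carrier-band tone of amplitude $A$ is recovered as $A$ for any
phase (the $2/N$ scaling makes the output physical mV). The default
window is $N = 960$ (20 cycles), giving a 100 Hz envelope rate — an
integer number of carrier cycles per window and comfortable oversampling
of the ≤7 Hz analysis band; windows do not overlap (hop $= N$), matching
the accumulate-then-output structure of an embedded implementation. The
demodulated DC term ($A_0$) is retained and removed downstream by the
baseline stage, mirroring the acquisition pipeline's order.

Out-of-band rejection: tones at multiples of $f_s/N = 100$ Hz from DC
are exactly orthogonal to the references over whole-cycle windows and
rejected to machine precision; at half-bin offsets (50, 150 Hz, …) the
Dirichlet sidelobe leaves a phase-dependent residual of up to ~3.3% of
the tone amplitude at $N = 960$. The 50 Hz mains tone is thus attenuated
by 30 dB or more, and its envelope-band alias is further removed by the
7 Hz low-pass.

## Cleaning chain

**Baseline suppression.** A symmetric triangular kernel (length 10 at
100 Hz, non-zero endpoints) has its mean subtracted and is normalized to
unit peak; its coefficients sum to zero, so a sliding dot product maps
any constant input to exactly zero and strongly attenuates slow drift
while passing the ~4 Hz pulse. Length 10 is the default analysis-rate
choice; lengths below 3 are rejected (a length-2 "triangle" degenerates
to the zero vector after mean removal). The operation is linear, and the
kernel is symmetric, so correlation and convolution coincide.

**Low-pass.** An order-100 windowed-sinc FIR (Hamming window, the
conventional default of `fir1`-style designers) with 7 Hz cutoff at the
100 Hz envelope rate. Taps are symmetrized exactly and rescaled to unity
DC gain; linear phase means every passband component is delayed by
exactly `order/2` samples, which the implementation compensates so
filtered and unfiltered traces stay aligned. The response is flat within
0.5 dB at 4 Hz and below −40 dB at 15 Hz.

**Edges.** Both stages use symmetric (mirror) padding for same-length
output. The first and last `order/2 + ceiling(kernel_length/2)` samples
(55 at the defaults) are flagged as transients in the processing log and
excluded from all feature windows.

**Gain compensation.** The unit-peak kernel normalization leaves the
cascade with non-unity, frequency-dependent passband gain (0.39 at 2 Hz,
1.42 at 4 Hz, 2.56 at 6 Hz). Amplitude features are therefore divided by
the cascade's gain at the *measured* dominant frequency, reconstructed
from the processing log, which restores physical mV exactly for
narrowband signals. For broadband (non-viable) signals a
single-frequency correction is approximate; with the band-limited drift
model above, the residual bias is small and conservative in practice.

## Time–frequency analysis

The STFT uses a 255-point Hanning window (without zero endpoints),
zero-padded to a 256-point DFT for radix-2 efficiency — bin width
100/256 ≈ 0.39 Hz — with a default hop of 1 sample (full temporal
resolution; configurable for speed) and a one-sided magnitude spectrum.
Stored magnitudes are raw $|{\rm DFT}|$ values; Parseval's identity is
kept testable through the documented two-sided reconstruction.

Derived quantities:

* **dominant frequency**: argmax of the time-averaged magnitude in
  1–15 Hz; ties break toward the lower frequency;
* **spectral concentration**: time-averaged energy within ±1 Hz of a
  centre frequency divided by the total in 0.5–15 Hz. Bins below 0.5 Hz
  are excluded everywhere so residual drift cannot dominate the
  denominator. An all-zero map returns 0 with a warning (rather than
  NaN), the defined degenerate value.

## Viability rule

Features over the steady region: dominant frequency, gain-compensated
peak-to-peak amplitude, concentration at the measured peak, and
periodicity — the maximum biased normalized autocorrelation over lags
corresponding to pulse rates 2–6 Hz (for a noiseless sinusoid of
frequency 4 Hz this is ≈ 0.97, the $1 - \ell/n$ bias of the estimator).

The decision is a transparent conjunction, each criterion recorded as
evidence:

| criterion | default | rationale |
|---|---|---|
| amplitude > `amplitude_min` | 0.7 mV | midpoint of the observed 0.4 / 1.0 mV gap; any value inside the gap gives identical calls on default simulations |
| dominant frequency ∈ `freq_band` | 2–6 Hz | band around the ≈4 Hz embryonic pulse |
| concentration ≥ `concentration_min` | 0.5 | pulsatile spectra concentrate ≥ 0.9; diffuse ones fall well below |
| periodicity ≥ `periodicity_min` | 0.3 | clear periodicity vs aperiodic fluctuation |

The reported discriminative features come without an explicit published
decision rule; this conjunction is the package's formalization, with
every threshold configurable.

**Capture** (multi-day monitoring) is deliberately weaker than
viability: an embryo-day counts as captured when the periodicity and
frequency-band criteria hold, with the amplitude criterion excluded,
because day-10 signals are weak but pulsatile. Missing embryo-day cells
are recorded as not captured, with a warning.

## Problem sizes and runtime choices

Default acquisitions are 10 s (960,000 raw samples, 1,000 envelope
samples), batches are 15 viable + 5 non-viable embryos, and monitoring
covers 15 embryos × days 10–14 (75 cells). The discrimination check runs
20 independently seeded batches. Unit tests use shorter 2–5 s
acquisitions and smaller batches where only mechanics are under test.

## Known limitations

* The non-viable "irregular fluctuation" spectrum is modelled as
  band-limited Gaussian noise; real decomposition artifacts may differ.
* Single-frequency gain compensation is exact only for narrowband
  signals; amplitudes of broadband signals carry a residual bias.
* The envelope rate (100 Hz) is the package's choice of demodulation
  window, and the kernel/STFT window lengths (10, 255 samples) are
  interpreted at that rate.
* The classifier is rule-based by design; no learned model is included.
* Hop-1 STFT at minutes-long records is memory-hungry; increase `hop`
  for long traces.
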