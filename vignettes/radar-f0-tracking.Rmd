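---
title: "Methods: radar vocal-fold vibration tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar vocal-fold vibration tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalradar)
```

## The measurement model

A continuous-wave radar transmits `cos(2πft + Φ(t))` toward the throat.
With the subject at nominal distance `d0` and vocal-fold displacement
`x(t)`, the received signal, downconverted through a quadrature mixer, is

    I(t) = cos(θ + 4πx(t)/λ + ΔΦ(t)),   Q(t) = sin(θ + 4πx(t)/λ + ΔΦ(t))

where `λ = c/f`, `θ = 4πd0/λ + θ0` is constant while the subject holds
still, and `ΔΦ(t) = Φ(t) − Φ(t − 2d0/c)` is the residual oscillator phase
noise, which is negligible at fixed short standoff because the two
evaluations of `Φ` almost cancel. Two modelling approximations are baked
into the simulator, matching the operating regime rather than full wave
propagation: the time-of-flight retardation is collapsed into the
constant `θ` (sub-nanosecond delays modulate nothing at baseband rates),
and `ΔΦ` is modelled as a low-pass random walk whose default level is
zero. The quadrature architecture matters: a single mixer channel loses
sensitivity at "null point" distances, whereas the pair `(I, Q)` encodes
the phase unambiguously at any distance.

Complex signal demodulation forms `S(t) = I + jQ = exp(j[θ + 4πx/λ + ΔΦ])`
and takes the unwrapped angle. This is an exact inversion — the
closed-loop test demands agreement to 1e-9 rad on noise-free simulated
recordings and observes ~1e-16 — and it discards the magnitude, so DC
offsets and amplitude drift never reach the later stages. Unwrapping
happens *before* any filtering: filtering a wrapped angle would tear the
waveform at every 2π crossing, which is why the band-pass operates on
the unwrapped phase rather than on complex `S(t)` (the alternative
reading; chosen here as the interpretation that keeps the signal real
and the filter conventional).

## What the simulator emulates, and what it does not

`synthesize_glottal_waveform()` produces a displacement whose phase is
the cumulative integral of a commanded F0 contour, shaped either as a
harmonic sum with configurable spectral rolloff (default 12 dB/octave,
five harmonics — a crude but spectrally honest glottal stand-in) or as a
raised-cosine pulse train. Both expose at least three harmonics to the
50–1500 Hz analysis band; peak displacement is capped at 10 mm and
defaults to the study conditions (0.5–2 mm). `simulate_utterance()`
assembles syllable-like voiced spans (cosine on/off ramps, ~65% duty),
a slow sinusoidal intonation contour inside 150–250 Hz with seeded
random rate and phase, and channel noise set by an SNR convention the
hardware literature leaves open: the additive white noise standard
deviation is the AC RMS of the noise-free in-phase channel over voiced
spans times `10^(−SNR/20)` (default 20 dB).

Deliberately *not* emulated: consonant articulation and unvoiced
turbulence, random body movement (the demodulation is known to be
sensitive to it; cancellation is out of scope), antenna/RF front-end
effects, room acoustics in the microphone channel (the synthetic mic is
a peak-normalised copy of the glottal excitation), and subject-to-subject
variability. Passing tests on this generator therefore demonstrate that
the *algorithm chain* is correct and noise-tolerant, not that the system
performs identically on human recordings.

## Variational Mode Decomposition

The phase signal is decomposed into `K` narrow-band modes by minimising
the summed bandwidth of the frequency-shifted analytic signals subject
to reconstruction, solved by ADMM in the Fourier domain. Per iteration
and mode:

* mode update — Wiener filter of the residual,
  `û_k ← (f̂ − Σ_{i≠k} û_i + λ̂/2) / (1 + 2α(ω − ω_k)²)`;
* centre update — power centroid `ω_k ← ∫ω|û_k|²dω / ∫|û_k|²dω` over
  `ω ≥ 0`;
* dual ascent — `λ̂ ← λ̂ + τ(f̂ − Σ û_k)`. The sign pairing with the
  `+λ̂/2` numerator is load-bearing: the opposite pairing turns the
  ascent into positive feedback and diverges within tens of iterations.

Numerical choices:

* **One-sidedness.** The analytic-signal multiplier is realised by
  zeroing negative frequencies; time-domain modes are rebuilt with
  conjugate-symmetric spectra so they are exactly real.
* **Boundaries.** The input is mirror-extended by half its length on
  each side and the centre section returned. Without this, edge
  discontinuities splatter across the spectrum and bias the centroids.
* **Uniform initialisation.** `ω_k = (k−1)·fs/(2K)` — K equally spaced
  values starting at 0, the reference practice. Midpoint spacing
  (strictly inside the band) was evaluated and rejected: when all signal
  content lies below the lowest initial centre, both modes can collapse
  onto the same tone and leave the fundamental unclaimed. Zero and
  seeded-random initialisation remain as options, and on well-separated
  tones all schemes reach the same mode set (tested).
* **Convergence.** `Σ_k ‖u_k^{n+1} − u_k^n‖² / ‖u_k^n‖² < tol`, with the
  denominator floored to avoid 0/0 on silent inputs (an all-zero signal
  converges in one iteration to all-zero modes). Defaults `tol = 1e-7`,
  cap 500 iterations; hitting the cap sets an explicit non-convergence
  flag and the per-iteration history is always returned.
* **Defaults** `α = 2000` (moderate bandwidth pressure; larger α gives
  measurably narrower modes), `τ = 0` (the multiplier stays frozen, so
  broadband noise is tolerated in the residual instead of being forced
  into the modes), `K = 2` (one vibration-bearing mode, one noise mode),
  no DC mode. These are the published operating settings of the
  radar-speech decomposition this package implements, and the config
  exposes all of them.

## References and mode selection

The microphone channel is framed (40 ms Hann, 10 ms hop) and the real
cepstrum peak is sought in the quefrency band for 50–500 Hz. Frame
voicing uses a robust prominence score, `(peak − median)/MAD` of the
in-band cepstrum, threshold 6.5. The plain z-score against mean/sd was
tried first and separates poorly because a genuine peak inflates the
standard deviation; with the MAD score, clean harmonic frames score ≥ 8
and white-noise frames ≤ ~5.5, so 6.5 splits them with margin on both
sides. Surviving values `f_v` average to `f̄_v`, exactly the arithmetic
mean of the returned set.

The vibration-bearing mode is `argmin_k |f̄_v − peak(u_k)|`, where
`peak(·)` is the frequency of the maximum-magnitude FFT bin (the
"average frequency" of a narrow-band mode; an interpretation, since a
spectrum maximum is the only reading that can be compared against a
frequency). Ties break to the lower index and are logged together with
all `|f̄_v − peak|` distances, making each selection auditable. When no
microphone is supplied the pipeline falls back to ground truth (if
given) and then to the cepstrum of the radar phase itself, recording
which reference was used.

The per-period "hand label" reference automates manual peak marking:
same-family extrema (peaks and valleys tracked separately — mixing the
families would halve every period) above 30% of the segment maximum,
refined by parabolic interpolation to beat the 1/fs quantisation, pruned
to a minimum spacing of one period at 500 Hz; each successive pair gives
`F0 = 1/Δt` at the pair midpoint.

## Tracking and scoring

The selected mode's instantaneous frequency is the derivative of its
analytic phase (central differences; one-sided at the ends). Samples
where the analytic amplitude drops below 10% of the segment maximum are
masked as invalid before smoothing — the phase derivative of a
near-zero-amplitude analytic signal is numerically explosive. Smoothing
is a rectangular moving average of width three dominant periods (the
dominant period is the reciprocal of the selected mode's spectral peak,
taken globally per segment for stability), NA-aware, shrinking at the
edges; a window longer than its segment degrades to the segment mean
with a warning.

Scoring follows the per-utterance relative error
`e = (100/N) Σ (f_r(t_n) − f_v[n])/f_v[n]`, matched by nearest
neighbour within half the reference spacing. `e` is a *signed* mean, so
symmetric deviations cancel; the report therefore carries the mean
absolute relative deviation alongside, and the package's own
end-to-end acceptance uses the absolute variant (the stricter of the
two) against the 10% bound.

## Problem sizes and runtime

The shipped tests and the acceptance script run entirely on synthetic
material: 1–2 s utterances at 8 kHz, 1 s tones/chirps at 1–8 kHz,
ten seeded two-tone decompositions, and twenty seeded noise
realisations for the selection-robustness estimate. These sizes keep a
full run in the tens of seconds on a single core while leaving every
estimate comfortably inside its tolerance; they are choices of this
package, and all scale up linearly through the same functions.

## Known limitations

* Real radar recordings contain body-sway and breathing phase drift far
  above the simulator's default; the 50 Hz high-pass removes slow drift
  but large sudden movements corrupt the phase outright.
* The synthetic microphone channel shares the radar's glottal source
  exactly, so cepstral reference quality on real acoustic speech (vocal
  tract filtering, consonants, reverberation) will be lower than in
  these tests.
* One utterance, one subject position: `θ` constant. Distance changes
  between utterances only shift `θ` and are harmless; within-utterance
  changes are body movement (above).
* `K = 2` is assumed sufficient (vibration + noise). Strongly voiced
  signals with powerful second harmonics inside the band may warrant
  `K = 3`; the solver is general even though the pipeline default is 2.
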