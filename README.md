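# vocalradar

Non-acoustic tracking of the time-varying speech fundamental frequency
(F0) from continuous-wave Doppler radar.

During voiced speech the vocal folds oscillate with a displacement of a
few millimetres. A 24-GHz continuous-wave radar pointed at the throat
sees that motion as a phase modulation of the reflected carrier: after
quadrature downconversion the baseband pair is

    I(t) = cos(θ + 4πx(t)/λ + ΔΦ(t))
    Q(t) = sin(θ + 4πx(t)/λ + ΔΦ(t))

with `x(t)` the fold displacement, `λ = c/f` the carrier wavelength
(12.5 mm at 24 GHz, so 1 mm of motion ≈ 1 rad of phase), `θ` the constant
phase set by the standoff distance, and `ΔΦ` residual phase noise.
Because `x(t)` is non-sinusoidal and its rate is the speech fundamental,
recovering the phase recovers a noise-immune, microphone-free F0 track —
useful where acoustic recordings drown in background noise or where fine
frequency-resolving power matters (e.g. tonal languages).

`vocalradar` implements the complete recovery pipeline plus a physics
simulator that generates every input the pipeline needs:

1. **Simulation** — `synthesize_glottal_waveform()` builds a harmonic-rich
   mm-scale displacement with a prescribed instantaneous F0 contour;
   `baseband_from_displacement()` applies the phase model above.
2. **Complex signal demodulation** — `complex_demodulate()` forms
   `S(t) = I + jQ` and unwraps its angle, inverting the model exactly and
   independently of DC offsets.
3. **Preprocessing** — `bandpass_filter()` (zero-phase Butterworth,
   50–1500 Hz) and `energy_segments()` (short-term-energy voiced-segment
   extraction).
4. **Variational Mode Decomposition** — `vmd_decompose()`, a from-scratch
   frequency-domain ADMM solver that splits the phase signal into K
   narrow-band modes `u_k` with centre frequencies `ω_k` (Wiener-filter
   mode updates, power-centroid frequency updates, optional dual ascent).
   Defaults: `α = 2000`, `τ = 0`, `K = 2`, `tol = 1e-7`, uniform init, no
   DC mode.
5. **Mode selection** — `select_vibration_mode()` picks
   `argmin_k |f̄_v − peak(u_k)|`, where `f̄_v` is the mean of the
   cepstrum F0 values of the paired microphone channel
   (`cepstrum_f0()`).
6. **Tracking** — `instantaneous_frequency()` (Hilbert analytic phase
   derivative) and `smooth_frequency()` (rectangular window spanning
   three dominant periods) give the time-varying vibration frequency;
   `hand_label_f0()` provides the per-period extremum-spacing reference
   and `relative_error()` the per-utterance score
   `e = (100/N) Σ (f_r(t_n) − f_v[n]) / f_v[n]` (plus its mean-absolute
   variant).

Everything is tibble-first and pipe-friendly; results support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(vocalradar)

cfg <- pipeline_config(seed = 7)
utt <- simulate_utterance(cfg, duration_s = 1.5, n_syllables = 2, snr_db = 20)
res <- track_recording(utt$recording, cfg, mic_audio = utt$mic_audio)
glance(res)
#> # A tibble: 2 x 9
#>   segment_id start_s end_s reference_source    reference_mean_hz selected_mode
#>        <int>   <dbl> <dbl> <chr>                           <dbl>         <int>
#> 1          1    0.12 0.635 microphone_cepstrum              169.             1
#> 2          2    0.87  1.38 microphone_cepstrum              199.             1
#> # i 3 more variables: dominant_frequency_hz <dbl>, vmd_iterations <int>,
#> #   vmd_converged <lgl>

truth <- dplyr::filter(tibble::as_tibble(utt$track), f0_hz > 0)
relative_error(res$track, truth[seq(1, nrow(truth), 80), ])
#> <evaluation_report> N = 98 reference points over 1.232 s (0 excluded)
#>   signed relative error e = -0.122%; mean |relative error| = 0.264%
```

Two voiced segments are found; in each, the first decomposed mode (peak
near the 169/199 Hz cepstral reference) is selected as the
vibration-bearing one and its smoothed instantaneous frequency tracks
the simulated contour to a fraction of a percent at 20 dB SNR.

The same workflow runs from a shell via the thin CLI:

```sh
Rscript inst/cli/vocalradar.R all --output-prefix demo --seed 7 --duration 1.5
```

which writes the stereo I/Q WAV, the synthetic microphone WAV, the
ground-truth CSV, the tracked F0 CSV, the segment table, a YAML log of
each mode-selection decision, and the evaluation summary.

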