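# Signal constructors shared across tests. These are built directly from
# first principles (not through the package's generator) so they can serve
# as independent oracles.

make_tone <- function(freq, fs = 8000, duration = 1, amplitude = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitude * cos(2 * pi * freq * t + phase)
}

# linear chirp f0 -> f1 over the duration; instantaneous frequency at time
# t is f0 + (f1 - f0) * t / duration
make_chirp <- function(f0, f1, fs = 8000, duration = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  cos(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * duration)))
}

# impulse-like harmonic pulse train at a constant fundamental (all
# harmonics up to n_harm, equal weight) -- a crude glottal stand-in with a
# strong cepstral peak at the period
make_pulse_train <- function(f0, fs = 8000, duration = 1, n_harm = 10) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- rep(0, length(t))
  for (h in seq_len(n_harm)) x <- x + cos(2 * pi * h * f0 * t)
  x / n_harm
}

# brute-force spectral peak over the magnitude spectrum (independent of
# mode_peak_frequency's internals)
fft_peak_hz <- function(x, fs) {
  mag <- Mod(stats::fft(x))
  half <- seq_len(floor(length(x) / 2) + 1)
  (which.max(mag[half]) - 1) * fs / length(x)
}

# top-n well-separated spectral peaks (for two-tone oracles)
fft_peaks_hz <- function(x, fs, n = 2, min_sep_hz = 20) {
  mag <- Mod(stats::fft(x))
  half <- seq_len(floor(length(x) / 2) + 1)
  mag <- mag[half]
  freqs <- (half - 1) * fs / length(x)
  found <- numeric(0)
  ord <- order(mag, decreasing = TRUE)
  for (i in ord) {
    if (all(abs(freqs[i] - found) >= min_sep_hz)) found <- c(found, freqs[i])
    if (length(found) == n) break
  }
  sort(found)
}

# rms of the steady-state middle portion (avoids filter edge transients)
mid_rms <- function(x, trim = 0.2) {
  n <- length(x)
  i <- seq(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  sqrt(mean(x[i]^2))
}

default_sim <- function(seed, duration_s = 1.2, n_syllables = 1, snr_db = 20) {
  cfg <- pipeline_config(seed = seed)
  utt <- simulate_utterance(cfg, duration_s = duration_s,
                            n_syllables = n_syllables, snr_db = snr_db)
  list(cfg = cfg, utt = utt)
}

truth_points <- function(utt, spacing_s = 0.01) {
  fs <- utt$sampling_rate
  step <- max(1L, round(spacing_s * fs))
  tr <- utt$track
  keep <- tr$f0_hz > 0
  tibble::tibble(time_s = tr$time_s[keep], f0_hz = tr$f0_hz[keep])[
    seq(1, sum(keep), by = step), ]
}
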