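# Glottal-displacement simulator and the CW-radar baseband phase model.
#
# A continuous-wave radar facing the throat sees the mm-scale vocal-fold
# displacement x(t) as a phase modulation of the reflected carrier. After
# quadrature downconversion the baseband pair is
#   I(t) = cos(theta + 4*pi*x(t)/lambda + dPhi(t))
#   Q(t) = sin(theta + 4*pi*x(t)/lambda + dPhi(t))
# where lambda = c/f is the carrier wavelength, theta the constant phase
# set by the nominal standoff distance, and dPhi(t) the residual phase
# noise. Everything downstream (demodulation, decomposition, tracking) is
# tested against waveforms produced here.

#' Radar configuration
#'
#' Parameters of the continuous-wave radar and its baseband digitiser.
#' The wavelength is derived from the carrier (`lambda = c / f`); the
#' constant phase offset is `theta = 4*pi*d0/lambda + theta0`, wrapped to
#' `(-pi, pi]`.
#'
#' @param carrier_frequency Carrier in Hz (default 24 GHz; at this band a
#'   1 mm displacement maps to about 1 rad of baseband phase).
#' @param nominal_distance_d0 Standoff distance radar-to-throat in m.
#' @param theta0 Additional constant phase in rad (mixer/LO offset).
#' @param residual_phase_noise_std Random-walk residual phase noise level,
#'   rad per sqrt(second); 0 disables.
#' @param additive_noise_std Std of white noise added to each baseband
#'   channel (channel units; the noise-free channels live on the unit
#'   circle).
#' @param sampling_rate Baseband sampling rate in Hz.
#' @return A `radar_config` list.
#' @export
radar_config <- function(carrier_frequency = 24e9,
                         nominal_distance_d0 = 0.4,
                         theta0 = 0,
                         residual_phase_noise_std = 0,
                         additive_noise_std = 0,
                         sampling_rate = 8000) {
  if (carrier_frequency <= 0) abort("carrier_frequency must be positive")
  if (nominal_distance_d0 < 0) abort("nominal_distance_d0 must be >= 0")
  if (residual_phase_noise_std < 0 || additive_noise_std < 0) {
    abort("noise standard deviations must be >= 0")
  }
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  wavelength <- SPEED_OF_LIGHT / carrier_frequency
  theta_raw <- 4 * pi * nominal_distance_d0 / wavelength + theta0
  theta <- atan2(sin(theta_raw), cos(theta_raw))
  structure(
    list(
      carrier_frequency = carrier_frequency,
      wavelength = wavelength,
      nominal_distance_d0 = nominal_distance_d0,
      theta0 = theta0,
      theta = theta,
      residual_phase_noise_std = residual_phase_noise_std,
      additive_noise_std = additive_noise_std,
      sampling_rate = sampling_rate
    ),
    class = "radar_config"
  )
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> %.3g GHz carrier (lambda %.4g mm), d0 %.3g m, fs %g Hz\n",
    x$carrier_frequency / 1e9, x$wavelength * 1e3, x$nominal_distance_d0,
    x$sampling_rate))
  cat(sprintf("  theta %.4g rad; phase-walk std %g rad/sqrt(s); channel noise std %g\n",
              x$theta, x$residual_phase_noise_std, x$additive_noise_std))
  invisible(x)
}

# cosine on/off ramps applied to each voiced run; avoids spectral clicks
ramped_envelope <- function(voiced, sampling_rate, ramp_s) {
  env <- as.numeric(voiced)
  if (!any(voiced)) return(env)
  r <- rle(as.logical(voiced))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nr <- max(1L, round(ramp_s * sampling_rate))
  for (j in which(r$values)) {
    len <- r$lengths[j]
    k <- min(nr, floor(len / 2))
    if (k > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(k) / (k + 1)))
      env[starts[j]:(starts[j] + k - 1)] <- ramp
      env[(ends[j] - k + 1):ends[j]] <- rev(ramp)
    }
  }
  env
}

#' Synthesize a non-sinusoidal glottal displacement waveform
#'
#' Generates a vocal-fold displacement x(t) whose instantaneous
#' fundamental follows `f0_contour`: the oscillator phase is the cumulative
#' integral of the contour, and the waveform is either a harmonic sum with
#' a prescribed spectral rolloff or a raised-cosine pulse train. Glottal
#' vibration is non-sinusoidal, so at least three harmonics are present.
#'
#' @param f0_contour Instantaneous fundamental in Hz, one value per sample;
#'   50-500 Hz wherever voiced.
#' @param peak_displacement Peak displacement in m, in (0, 0.01] (vocal-fold
#'   motion reaches only a few millimetres).
#' @param pulse_shape `"sum_of_harmonics"` or `"raised_cosine_pulse_train"`.
#' @param harmonic_rolloff Spectral rolloff of the harmonic sum in
#'   dB/octave (ignored for the pulse train).
#' @param sampling_rate Hz; must be at least 4 x max(f0) so the required
#'   harmonics do not alias.
#' @param voiced_mask Logical per sample; silent (zero displacement) where
#'   `FALSE`. Default: voiced everywhere.
#' @param n_harmonics Number of harmonics in the harmonic sum (>= 3),
#'   capped below Nyquist.
#' @param duty_cycle Open-phase fraction of the raised-cosine pulse.
#' @param ramp_s Cosine onset/offset ramp applied at voicing boundaries, s.
#' @return A `vibration_track` tibble: `time_s`, `displacement_m`,
#'   `f0_hz` (ground truth, 0 in silent spans), `envelope_m`.
#' @export
synthesize_glottal_waveform <- function(f0_contour,
                                        peak_displacement = 1e-3,
                                        pulse_shape = c("sum_of_harmonics",
                                                        "raised_cosine_pulse_train"),
                                        harmonic_rolloff = 12,
                                        sampling_rate = 8000,
                                        voiced_mask = NULL,
                                        n_harmonics = 5,
                                        duty_cycle = 0.5,
                                        ramp_s = 0.01) {
  pulse_shape <- match.arg(pulse_shape)
  check_finite(f0_contour, "f0_contour")
  n <- length(f0_contour)
  if (n == 0) abort("f0_contour is empty")
  voiced_mask <- voiced_mask %||% rep(TRUE, n)
  if (length(voiced_mask) != n) abort("voiced_mask must match f0_contour length")
  if (any(voiced_mask) &&
      (any(f0_contour[voiced_mask] < 50) || any(f0_contour[voiced_mask] > 500))) {
    abort("f0_contour must lie in [50, 500] Hz on voiced samples")
  }
  if (peak_displacement <= 0 || peak_displacement > 0.01) {
    abort("peak_displacement must be in (0, 0.01] m")
  }
  f0max <- if (any(voiced_mask)) max(f0_contour[voiced_mask]) else 0
  if (any(voiced_mask) && sampling_rate < 4 * f0max) {
    abort(sprintf(
      "sampling_rate %g Hz < 4 x max f0 (%g Hz): harmonics would alias",
      sampling_rate, f0max))
  }

  time_s <- (seq_len(n) - 1) / sampling_rate
  phase <- 2 * pi * cumsum(f0_contour) / sampling_rate
  env01 <- ramped_envelope(voiced_mask, sampling_rate, ramp_s)

  if (pulse_shape == "sum_of_harmonics") {
    n_h <- max(3L, as.integer(n_harmonics))
    if (f0max > 0) n_h <- min(n_h, max(3L, floor(0.95 * sampling_rate / 2 / f0max)))
    amps <- 10^(-harmonic_rolloff * log2(seq_len(n_h)) / 20)
    x0 <- rep(0, n)
    for (h in seq_len(n_h)) x0 <- x0 + amps[h] * cos(h * phase)
    x0 <- x0 / sum(amps)  # |x0| <= 1
  } else {
    # raised-cosine pulse centred at phase = 0 (mod 2*pi), zero elsewhere
    w <- atan2(sin(phase), cos(phase))  # wrapped to (-pi, pi]
    x0 <- ifelse(abs(w) < duty_cycle * pi, 0.5 * (1 + cos(w / duty_cycle)), 0)
  }

  envelope_m <- peak_displacement * env01
  displacement <- envelope_m * x0
  true_f0 <- ifelse(envelope_m > 0, f0_contour, 0)

  new_signal_tbl(
    tibble::tibble(time_s = time_s, displacement_m = displacement,
                   f0_hz = true_f0, envelope_m = envelope_m),
    sampling_rate, "vibration_track"
  )
}

#' Simulate the quadrature baseband induced by a displacement track
#'
#' Applies the CW-radar phase model: the displacement enters the baseband
#' pair as a phase `theta + 4*pi*x(t)/lambda + dPhi(t)`, where `dPhi` is a
#' slow random walk of configurable level (0 by default, the residual
#' phase noise being negligible at a fixed standoff), followed by optional
#' additive white noise on each channel.
#'
#' @param track A `vibration_track` (from [synthesize_glottal_waveform()]).
#' @param config A [radar_config()]; its `sampling_rate` must match the track.
#' @param seed Optional integer seed for the noise draws (the global RNG
#'   state is untouched).
#' @return A `quadrature_recording` tibble: `time_s`, `i`, `q`.
#' @export
baseband_from_displacement <- function(track, config = radar_config(), seed = NULL) {
  fs <- sampling_rate(track)
  if (abs(fs - config$sampling_rate) > 1e-9 * fs) {
    abort(sprintf("track sampled at %g Hz but config expects %g Hz",
                  fs, config$sampling_rate))
  }
  n <- nrow(track)
  gen <- function() {
    dphi <- if (config$residual_phase_noise_std > 0) {
      cumsum(stats::rnorm(n, 0, config$residual_phase_noise_std / sqrt(fs)))
    } else 0
    phi <- config$theta + 4 * pi * track$displacement_m / config$wavelength + dphi
    i <- cos(phi); q <- sin(phi)
    if (config$additive_noise_std > 0) {
      i <- i + stats::rnorm(n, 0, config$additive_noise_std)
      q <- q + stats::rnorm(n, 0, config$additive_noise_std)
    }
    list(i = i, q = q)
  }
  iq <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  new_signal_tbl(
    tibble::tibble(time_s = track$time_s, i = iq$i, q = iq$q),
    fs, "quadrature_recording"
  )
}

#' Write a simulated recording to disk as WAV + ground-truth CSV
#'
#' Writes three files: `<prefix>_iq.wav` (stereo float32, channel 1 = I,
#' channel 2 = Q), `<prefix>_mic.wav` (mono float32 microphone audio
#' rendered from the same glottal excitation, peak-normalised to 0.9), and
#' `<prefix>_truth.csv` (`time_s`, `f0_hz`, `displacement_m`).
#'
#' @param recording A `quadrature_recording`.
#' @param mic_track The `vibration_track` the recording was generated from.
#' @param path_prefix Output path prefix (directories must exist).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(recording, mic_track, path_prefix) {
  if (nrow(recording) == 0) abort("recording is empty")
  fs <- sampling_rate(recording)
  paths <- c(iq = paste0(path_prefix, "_iq.wav"),
             mic = paste0(path_prefix, "_mic.wav"),
             truth = paste0(path_prefix, "_truth.csv"))
  write_wav(cbind(recording$i, recording$q), fs, paths[["iq"]])
  peak <- max(abs(mic_track$displacement_m))
  audio <- if (peak > 0) 0.9 * mic_track$displacement_m / peak else
    rep(0, nrow(mic_track))
  write_wav(audio, sampling_rate(mic_track), paths[["mic"]])
  readr::write_csv(
    tibble::tibble(time_s = mic_track$time_s, f0_hz = mic_track$f0_hz,
                   displacement_m = mic_track$displacement_m),
    paths[["truth"]])
  invisible(paths)
}
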