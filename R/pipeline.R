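# Configuration, the end-to-end utterance simulator, the full tracking
# pipeline (demodulate -> band-pass -> segment -> decompose -> select ->
# instantaneous frequency -> smooth), and CLI-facing wrappers.

#' Pipeline configuration
#'
#' One nested configuration object covering every stage; round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param radar A [radar_config()].
#' @param vmd A [vmd_config()].
#' @param bandpass_low,bandpass_high Band edges, Hz.
#' @param segmentation Named list: `frame_length_s`, `hop_s`,
#'   `threshold_ratio`, `minimum_duration_s`.
#' @param cepstrum Named list: `frame_length_s`, `hop_s`, `f0_min`,
#'   `f0_max`, `voicing_threshold`.
#' @param smoothing_multiplier Smoothing window in dominant periods.
#' @param seed Integer seed driving all randomness in the workflow.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(radar = radar_config(),
                            vmd = vmd_config(),
                            bandpass_low = 50, bandpass_high = 1500,
                            segmentation = list(frame_length_s = 0.025,
                                                hop_s = 0.010,
                                                threshold_ratio = 0.1,
                                                minimum_duration_s = 0.05),
                            cepstrum = list(frame_length_s = 0.04,
                                            hop_s = 0.01, f0_min = 50,
                                            f0_max = 500,
                                            voicing_threshold = 6.5),
                            smoothing_multiplier = 3,
                            seed = 1L) {
  structure(
    list(radar = radar, vmd = vmd,
         bandpass_low = bandpass_low, bandpass_high = bandpass_high,
         segmentation = segmentation, cepstrum = cepstrum,
         smoothing_multiplier = smoothing_multiplier,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- list(
    radar = config$radar[c("carrier_frequency", "nominal_distance_d0",
                           "theta0", "residual_phase_noise_std",
                           "additive_noise_std", "sampling_rate")],
    vmd = unclass(config$vmd),
    bandpass_low = config$bandpass_low, bandpass_high = config$bandpass_high,
    segmentation = config$segmentation, cepstrum = config$cepstrum,
    smoothing_multiplier = config$smoothing_multiplier, seed = config$seed
  )
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    radar = do.call(radar_config, y$radar),
    vmd = do.call(vmd_config, y$vmd),
    bandpass_low = y$bandpass_low, bandpass_high = y$bandpass_high,
    segmentation = y$segmentation, cepstrum = y$cepstrum,
    smoothing_multiplier = y$smoothing_multiplier, seed = y$seed
  )
}

#' Simulate a voiced utterance and its radar recording
#'
#' Generates the study conditions end to end: a piecewise-smooth
#' fundamental contour between 150 and 250 Hz, one or more voiced
#' syllables separated by silence, a per-utterance peak displacement
#' drawn between 0.5 and 2 mm, the induced quadrature baseband at a
#' channel SNR of `snr_db` (additive white noise scaled to the AC RMS of
#' the noise-free in-phase channel over voiced spans), and a synthetic
#' microphone rendering of the same glottal excitation.
#'
#' @param config A [pipeline_config()]; its `radar` and `seed` are used.
#' @param duration_s Total duration, s (> 0).
#' @param n_syllables Number of voiced spans.
#' @param snr_db Baseband channel SNR in dB (Inf for noise-free).
#' @param f0_range Bounds of the fundamental contour, Hz.
#' @param displacement_range Peak-displacement bounds, m.
#' @param pulse_shape Passed to [synthesize_glottal_waveform()].
#' @param seed Overrides `config$seed` when given.
#' @return A `radar_utterance` list: `track` (vibration_track),
#'   `recording` (quadrature_recording), `mic_audio` (numeric),
#'   `sampling_rate`, `params`.
#' @export
simulate_utterance <- function(config = pipeline_config(), duration_s = 2,
                               n_syllables = 2, snr_db = 20,
                               f0_range = c(150, 250),
                               displacement_range = c(0.5e-3, 2e-3),
                               pulse_shape = "sum_of_harmonics",
                               seed = NULL) {
  if (duration_s <= 0) abort("duration_s must be > 0")
  if (n_syllables < 1) abort("n_syllables must be >= 1")
  seed <- seed %||% config$seed
  fs <- config$radar$sampling_rate
  n <- round(duration_s * fs)
  if (n < 16) abort("duration_s too short at this sampling rate")

  sim <- withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    # smooth contour: slow sinusoid with random phase/rate inside the band
    mid <- mean(f0_range); half <- diff(f0_range) / 2
    rate <- stats::runif(1, 0.4, 1.0)     # Hz, slow intonation movement
    ph <- stats::runif(1, 0, 2 * pi)
    f0 <- mid + 0.9 * half * sin(2 * pi * rate * t + ph)

    # evenly spaced syllables filling ~65% of the duration
    voiced <- rep(FALSE, n)
    slot <- duration_s / n_syllables
    for (k in seq_len(n_syllables)) {
      a <- (k - 1) * slot + 0.18 * slot
      b <- k * slot - 0.17 * slot
      voiced[t >= a & t < b] <- TRUE
    }
    peak <- stats::runif(1, displacement_range[1], displacement_range[2])
    track <- synthesize_glottal_waveform(
      f0, peak_displacement = peak, pulse_shape = pulse_shape,
      sampling_rate = fs, voiced_mask = voiced)

    clean <- baseband_from_displacement(track, config$radar)
    noise_sd <- 0
    if (is.finite(snr_db)) {
      vo <- track$envelope_m > 0
      ac <- clean$i[vo] - mean(clean$i[vo])
      noise_sd <- sqrt(mean(ac^2)) * 10^(-snr_db / 20)
    }
    rec <- clean
    if (noise_sd > 0) {
      rec$i <- rec$i + stats::rnorm(n, 0, noise_sd)
      rec$q <- rec$q + stats::rnorm(n, 0, noise_sd)
    }
    peak_d <- max(abs(track$displacement_m))
    mic <- if (peak_d > 0) 0.9 * track$displacement_m / peak_d else rep(0, n)
    list(track = track, recording = rec, mic_audio = mic,
         params = list(seed = seed, snr_db = snr_db, noise_sd = noise_sd,
                       peak_displacement_m = peak, f0_range = f0_range))
  })
  structure(c(sim, list(sampling_rate = fs)), class = "radar_utterance")
}

#' Run the full radar F0-tracking pipeline on a recording
#'
#' Demodulates the quadrature pair, band-passes the unwrapped phase,
#' extracts voiced segments by short-term energy, and per segment:
#' decomposes with VMD, selects the vibration-bearing mode against the
#' acoustic reference mean, computes the Hilbert instantaneous frequency
#' and smooths it over three dominant periods.
#'
#' The reference mean comes from the cepstrum of `mic_audio` when given,
#' else from `truth` (a data frame with `time_s`, `f0_hz`), else from the
#' cepstrum of the radar phase signal itself (logged as a fallback).
#'
#' @param recording A `quadrature_recording`.
#' @param config A [pipeline_config()].
#' @param mic_audio Optional microphone samples at the same rate.
#' @param truth Optional ground-truth F0 table.
#' @return A `radar_track_result`: list with `track` (f0_track),
#'   `segments` (segment_table), `phase` (filtered phase_signal), `log`
#'   (per-segment tibble: reference mean, selected mode, peak distances,
#'   iterations, convergence), `vmd` (list of `vmd_result`).
#' @export
track_recording <- function(recording, config = pipeline_config(),
                            mic_audio = NULL, truth = NULL) {
  fs <- sampling_rate(recording)
  phase <- complex_demodulate(recording)
  filtered <- bandpass_filter(phase, config$bandpass_low, config$bandpass_high)
  segments <- energy_segments(
    filtered,
    frame_length_s = config$segmentation$frame_length_s,
    hop_s = config$segmentation$hop_s,
    threshold_ratio = config$segmentation$threshold_ratio,
    minimum_duration_s = config$segmentation$minimum_duration_s)
  vseg <- voiced_segments(segments)

  track_rows <- list(); log_rows <- list(); vmds <- list()
  for (si in seq_len(nrow(vseg))) {
    a <- max(1L, floor(vseg$start_s[si] * fs) + 1L)
    b <- min(nrow(filtered), ceiling(vseg$end_s[si] * fs))
    seg_phase <- filtered$phase_rad[a:b]
    seg_times <- filtered$time_s[a:b]
    if (length(seg_phase) < 16) next

    ref_source <- "radar_phase_cepstrum"
    fbar <- NA_real_
    cep_args <- config$cepstrum
    get_fbar <- function(x) {
      f0s <- cepstrum_f0(x, fs,
                         frame_length_s = cep_args$frame_length_s,
                         hop_s = cep_args$hop_s, f0_min = cep_args$f0_min,
                         f0_max = cep_args$f0_max,
                         voicing_threshold = cep_args$voicing_threshold)
      f0_mean(f0s)
    }
    if (!is.null(mic_audio)) {
      fbar <- tryCatch(get_fbar(mic_audio[a:b]), error = function(e) NA_real_)
      ref_source <- "microphone_cepstrum"
    }
    if (is.na(fbar) && !is.null(truth)) {
      tv <- truth$f0_hz[truth$time_s >= seg_times[1] & truth$time_s <= seg_times[length(seg_times)]]
      tv <- tv[is.finite(tv) & tv > 0]
      if (length(tv)) { fbar <- mean(tv); ref_source <- "ground_truth" }
    }
    if (is.na(fbar)) {
      fbar <- tryCatch(get_fbar(seg_phase), error = function(e) NA_real_)
      ref_source <- "radar_phase_cepstrum"
    }
    if (is.na(fbar)) {
      warn(sprintf("segment %d: no usable F0 reference; skipping", si))
      next
    }

    dec <- vmd_decompose(seg_phase, config$vmd, sampling_rate = fs,
                         seed = config$seed)
    if (!dec$converged) {
      warn(sprintf("segment %d: VMD did not converge in %d iterations (final change %.3g)",
                   si, dec$iterations, utils::tail(dec$convergence_history, 1)))
    }
    sel <- select_vibration_mode(dec, fbar)
    dom_f <- attr(sel, "peak_frequencies_hz")[sel]
    raw <- instantaneous_frequency(dec$modes[, sel], fs, times = seg_times,
                                   segment_id = si)
    smoothed <- smooth_frequency(raw, 1 / dom_f,
                                 smoothing_multiplier = config$smoothing_multiplier)
    track_rows[[length(track_rows) + 1]] <- smoothed
    vmds[[length(vmds) + 1]] <- dec
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      segment_id = si, start_s = vseg$start_s[si], end_s = vseg$end_s[si],
      reference_source = ref_source, reference_mean_hz = fbar,
      selected_mode = as.integer(sel),
      mode_peaks_hz = list(attr(sel, "peak_frequencies_hz")),
      mode_distances_hz = list(attr(sel, "distances_hz")),
      dominant_frequency_hz = dom_f,
      vmd_iterations = dec$iterations, vmd_converged = dec$converged
    )
  }

  track <- if (length(track_rows)) dplyr::bind_rows(track_rows)
  else tibble::tibble(time_s = numeric(), f0_hz = numeric(),
                      source = character(), segment_id = integer())
  structure(
    list(track = tibble::new_tibble(track, nrow = nrow(track), class = "f0_track"),
         segments = segments, phase = filtered,
         log = dplyr::bind_rows(log_rows), vmd = vmds,
         sampling_rate = fs, config = config),
    class = "radar_track_result"
  )
}

#' @export
print.radar_track_result <- function(x, ...) {
  nseg <- nrow(voiced_segments(x$segments))
  cat(sprintf("<radar_track_result> %d voiced segment(s), %d track samples at %g Hz\n",
              nseg, sum(is.finite(x$track$f0_hz)), x$sampling_rate))
  if (nrow(x$log)) {
    cat(sprintf("  segment reference means (Hz): %s\n",
                paste(signif(x$log$reference_mean_hz, 4), collapse = ", ")))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# CLI-facing wrappers (the inst/cli/vocalradar.R script is a thin shell
# over these three functions)

#' Simulate an utterance and write the fixture files
#'
#' Writes `<prefix>_iq.wav`, `<prefix>_mic.wav` and `<prefix>_truth.csv`.
#' All randomness flows from `config$seed`: equal configs give
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_prefix Path prefix for the written files.
#' @param duration_s,n_syllables,snr_db Passed to [simulate_utterance()].
#' @return Named character vector of paths, invisibly.
#' @export
cli_simulate <- function(config = pipeline_config(), output_prefix,
                         duration_s = 2, n_syllables = 2, snr_db = 20) {
  utt <- simulate_utterance(config, duration_s = duration_s,
                            n_syllables = n_syllables, snr_db = snr_db)
  write_fixture(utt$recording, utt$track, output_prefix)
}

#' Track a recorded (or simulated) I/Q WAV and write the results
#'
#' Runs the full pipeline and writes `<prefix>_track.csv` (`time_s`,
#' `f0_hz`, `source`, `segment_id`), `<prefix>_segments.csv` and
#' `<prefix>_log.yaml` (per-segment reference mean, the
#' `|f_ref - peak(u_k)|` distances behind each mode selection, VMD
#' iteration counts and convergence flags).
#'
#' @param iq_wav Stereo I/Q WAV path.
#' @param config A [pipeline_config()].
#' @param output_prefix Path prefix for outputs.
#' @param mic_wav Optional mono microphone WAV (preferred F0 reference).
#' @param truth_csv Optional ground-truth CSV (`time_s`, `f0_hz`).
#' @return The `radar_track_result`, invisibly.
#' @export
cli_track <- function(iq_wav, config = pipeline_config(), output_prefix,
                      mic_wav = NULL, truth_csv = NULL) {
  rec <- read_quadrature_wav(iq_wav)
  mic <- if (!is.null(mic_wav)) as.vector(read_wav(mic_wav)$samples[, 1])
  truth <- if (!is.null(truth_csv)) {
    readr::read_csv(truth_csv, show_col_types = FALSE)
  }
  res <- track_recording(rec, config, mic_audio = mic, truth = truth)
  readr::write_csv(res$track, paste0(output_prefix, "_track.csv"))
  readr::write_csv(res$segments, paste0(output_prefix, "_segments.csv"))
  log <- res$log
  if (nrow(log)) {
    log$mode_peaks_hz <- vapply(log$mode_peaks_hz, paste, character(1), collapse = ";")
    log$mode_distances_hz <- vapply(log$mode_distances_hz, paste, character(1), collapse = ";")
  }
  yaml::write_yaml(lapply(split(log, seq_len(max(nrow(log), 0))), as.list),
                   paste0(output_prefix, "_log.yaml"))
  invisible(res)
}

#' Score a radar track CSV against a reference CSV
#'
#' Computes the per-utterance signed mean relative error and its
#' mean-absolute variant, and writes a one-row summary CSV.
#'
#' @param radar_track_csv Radar track CSV (`time_s`, `f0_hz`).
#' @param reference_csv Reference CSV (`time_s`, `f0_hz`); hand-label
#'   track, cepstrum set or ground truth.
#' @param output Output CSV path.
#' @return The `evaluation_report`, invisibly.
#' @export
cli_evaluate <- function(radar_track_csv, reference_csv, output) {
  rad <- readr::read_csv(radar_track_csv, show_col_types = FALSE)
  ref <- readr::read_csv(reference_csv, show_col_types = FALSE)
  if (nrow(ref) == 0) abort(sprintf("reference CSV '%s' is empty", reference_csv))
  rep <- relative_error(rad, ref)
  readr::write_csv(
    tibble::tibble(e_signed_pct = rep$e_signed_pct, e_abs_pct = rep$e_abs_pct,
                   n_reference_points = rep$n_used,
                   n_excluded = rep$n_excluded, duration_s = rep$duration_s),
    output)
  invisible(rep)
}
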