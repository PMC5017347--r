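# Mode selection, Hilbert instantaneous-frequency tracking, smoothing,
# and relative-error scoring against a reference track.

#' Select the vibration-bearing mode
#'
#' Picks the decomposed mode whose spectral-peak frequency is closest to
#' the acoustic reference mean: `argmin_k | f_ref - peak(u_k) |`. Ties
#' break toward the lower index and are reported.
#'
#' @param result A `vmd_result`.
#' @param reference_mean Reference mean F0 in Hz (> 0), typically
#'   [f0_mean()] of a [cepstrum_f0()] set.
#' @return Integer mode index with attributes `peak_frequencies_hz`,
#'   `distances_hz` and `tie` (logical).
#' @export
select_vibration_mode <- function(result, reference_mean) {
  if (!inherits(result, "vmd_result")) abort("result must be a vmd_result")
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    abort("reference_mean must be a positive frequency in Hz")
  }
  K <- ncol(result$modes)
  peaks <- vapply(seq_len(K), function(k) {
    m <- result$modes[, k]
    if (all(m == 0)) NA_real_ else mode_peak_frequency(m, result$sampling_rate)
  }, numeric(1))
  if (all(is.na(peaks))) {
    abort("all modes are identically zero: nothing to select",
          class = "vocalradar_zero_mode")
  }
  dist <- abs(reference_mean - peaks)
  best <- min(dist, na.rm = TRUE)
  hits <- which(abs(dist - best) < 1e-12)
  tie <- length(hits) > 1
  if (tie) {
    inform(sprintf(
      "mode selection tie at |f_ref - peak| = %.6g Hz (modes %s); taking mode %d",
      best, paste(hits, collapse = ", "), hits[1]))
  }
  structure(hits[1], peak_frequencies_hz = peaks, distances_hz = dist, tie = tie)
}

#' Instantaneous frequency via the Hilbert transform
#'
#' Builds the analytic signal, unwraps its phase and differentiates
#' (central differences in the interior, one-sided at the ends):
#' `f(t) = (1/2pi) d phi / dt`. Where the analytic amplitude falls below
#' `amplitude_mask_ratio` times its maximum, the phase derivative is
#' unreliable and the estimate is marked invalid (`NA`).
#'
#' @param mode Real numeric series (one decomposed mode over one voiced
#'   segment).
#' @param sampling_rate Hz.
#' @param times Optional time stamps (s); default starts at 0.
#' @param amplitude_mask_ratio Relative analytic-amplitude floor.
#' @param segment_id Segment identifier carried through to the track.
#' @return An `f0_track` tibble: `time_s`, `f0_hz` (NA where masked),
#'   `source = "radar"`, `segment_id`.
#' @export
instantaneous_frequency <- function(mode, sampling_rate, times = NULL,
                                    amplitude_mask_ratio = 0.1,
                                    segment_id = 1L) {
  check_finite(mode, "mode")
  n <- length(mode)
  if (n < 3) abort("mode too short for instantaneous frequency")
  if (all(mode == 0)) abort("mode is identically zero on this span",
                            class = "vocalradar_zero_mode")
  z <- analytic_signal(mode)
  amp <- Mod(z)
  phi <- unwrap_phase(Arg(z))
  freq <- pracma::gradient(phi, 1 / sampling_rate) / (2 * pi)
  freq[amp < amplitude_mask_ratio * max(amp)] <- NA_real_
  times <- times %||% ((seq_len(n) - 1) / sampling_rate)
  out <- tibble::tibble(time_s = times, f0_hz = freq,
                        source = "radar", segment_id = segment_id)
  tibble::new_tibble(out, nrow = n, class = "f0_track")
}

#' Smooth a frequency track with a rectangular window
#'
#' Moving average with a rectangular window of width
#' `T = smoothing_multiplier x dominant_period_s` (three dominant
#' oscillation periods by default), suppressing the sample-to-sample
#' jitter that noise and numerical differentiation induce. Invalid (`NA`)
#' samples are excluded from each window's average; near the track edges
#' the window shrinks to the available samples. If the window exceeds a
#' segment's length the segment-wide mean is returned with a warning.
#'
#' @param track An `f0_track` (uniformly sampled within each segment).
#' @param dominant_period_s Dominant oscillatory period of the selected
#'   mode, s (reciprocal of its spectral-peak frequency).
#' @param smoothing_multiplier Window width in dominant periods.
#' @return The smoothed `f0_track`.
#' @export
smooth_frequency <- function(track, dominant_period_s, smoothing_multiplier = 3) {
  if (dominant_period_s <= 0) abort("dominant_period_s must be > 0")
  if (nrow(track) == 0) return(track)
  fs <- 1 / median(diff(track$time_s[track$segment_id == track$segment_id[1]]))
  width <- max(1L, round(smoothing_multiplier * dominant_period_s * fs))
  smoothed <- track
  for (sid in unique(track$segment_id)) {
    sel <- track$segment_id == sid
    x <- track$f0_hz[sel]
    if (width >= sum(sel)) {
      warn(sprintf("smoothing window (%d samples) exceeds segment %s (%d samples); using the segment mean",
                   width, sid, sum(sel)))
      smoothed$f0_hz[sel] <- mean(x, na.rm = TRUE)
    } else {
      smoothed$f0_hz[sel] <- rolling_mean_na(x, width)
    }
  }
  smoothed
}

#' Relative error of a radar track against a discrete reference
#'
#' For each reference point (t_n, f_v\[n\]) the radar track value f_r(t_n)
#' is taken from the nearest track sample within `match_tolerance_s`
#' (half the median reference spacing by default); points outside
#' coverage are excluded and counted. The headline score is the signed
#' mean relative deviation
#' `e = 100/N * sum (f_r(t_n) - f_v[n]) / f_v[n]` (percent); because
#' symmetric deviations cancel in the signed mean, the mean absolute
#' relative deviation is reported alongside.
#'
#' @param radar An `f0_track` (the smoothed radar estimate).
#' @param reference A discrete reference: any data frame with `time_s` and
#'   `f0_hz` (hand-label track, cepstrum set, or ground truth).
#' @param match_tolerance_s Maximum |t_track - t_n| for a match, s.
#' @return An `evaluation_report`: list with `points` (per-point tibble),
#'   `e_signed_pct`, `e_abs_pct`, `n_used`, `n_excluded`, `duration_s`.
#' @export
relative_error <- function(radar, reference, match_tolerance_s = NULL) {
  if (nrow(reference) == 0) abort("reference track is empty")
  ref <- dplyr::filter(reference, is.finite(.data$f0_hz), .data$f0_hz > 0)
  if (nrow(ref) == 0) abort("reference has no positive finite F0 values")
  rad <- dplyr::filter(radar, is.finite(.data$f0_hz))
  if (nrow(rad) == 0) abort("radar track has no valid F0 values")
  if (min(ref$time_s) > max(rad$time_s) || max(ref$time_s) < min(rad$time_s)) {
    abort(sprintf(
      "disjoint time ranges: radar [%.3f, %.3f] s vs reference [%.3f, %.3f] s",
      min(rad$time_s), max(rad$time_s), min(ref$time_s), max(ref$time_s)))
  }
  if (is.null(match_tolerance_s)) {
    match_tolerance_s <- if (nrow(ref) > 1) median(diff(sort(ref$time_s))) / 2
    else 0.02
  }
  idx <- findInterval(ref$time_s, rad$time_s, all.inside = TRUE)
  # nearest of the two bracketing samples
  idx2 <- pmin(idx + 1L, nrow(rad))
  use_hi <- abs(rad$time_s[idx2] - ref$time_s) < abs(rad$time_s[idx] - ref$time_s)
  near <- ifelse(use_hi, idx2, idx)
  dt <- abs(rad$time_s[near] - ref$time_s)
  matched <- dt <= match_tolerance_s

  points <- tibble::tibble(
    time_s = ref$time_s[matched],
    f0_reference_hz = ref$f0_hz[matched],
    f0_radar_hz = rad$f0_hz[near[matched]],
    relative_deviation = (rad$f0_hz[near[matched]] - ref$f0_hz[matched]) /
      ref$f0_hz[matched]
  )
  if (nrow(points) == 0) abort("no reference point falls within radar coverage")
  structure(
    list(
      points = points,
      e_signed_pct = mean(points$relative_deviation) * 100,
      e_abs_pct = mean(abs(points$relative_deviation)) * 100,
      n_used = nrow(points),
      n_excluded = sum(!matched),
      duration_s = diff(range(points$time_s))
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> N = %d reference points over %.3f s (%d excluded)\n",
              x$n_used, x$duration_s, x$n_excluded))
  cat(sprintf("  signed relative error e = %.3f%%; mean |relative error| = %.3f%%\n",
              x$e_signed_pct, x$e_abs_pct))
  invisible(x)
}
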