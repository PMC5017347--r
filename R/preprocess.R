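# Complex signal demodulation, band-pass filtering and short-term-energy
# voiced-segment extraction.

#' Complex signal demodulation of a quadrature recording
#'
#' Forms S(t) = I(t) + jQ(t) and returns its unwrapped argument, which for
#' the CW-radar model equals `theta + 4*pi*x(t)/lambda + dPhi(t)`. The
#' magnitude is discarded: taking the angle makes the method insensitive
#' to amplitude and, together with the later band-pass, to DC offsets.
#' Samples where both channels are (numerically) zero have no defined
#' angle; the complex signal is linearly interpolated across them before
#' the angle is taken, and their count is recorded in the
#' `n_interpolated` attribute.
#'
#' @param recording A `quadrature_recording` tibble (`time_s`, `i`, `q`).
#' @return A `phase_signal` tibble: `time_s`, `phase_rad`.
#' @export
complex_demodulate <- function(recording) {
  check_finite(recording$i, "I channel")
  check_finite(recording$q, "Q channel")
  fs <- sampling_rate(recording)
  re <- recording$i
  im <- recording$q
  mag <- sqrt(re^2 + im^2)
  bad <- mag < 1e-12
  if (any(bad)) {
    if (all(bad)) abort("all samples have zero magnitude; no phase to demodulate")
    idx <- seq_along(re)
    re[bad] <- approx(idx[!bad], re[!bad], idx[bad], rule = 2)$y
    im[bad] <- approx(idx[!bad], im[!bad], idx[bad], rule = 2)$y
  }
  phase <- unwrap_phase(atan2(im, re))
  out <- new_signal_tbl(
    tibble::tibble(time_s = recording$time_s, phase_rad = phase),
    fs, "phase_signal"
  )
  attr(out, "n_interpolated") <- sum(bad)
  out
}

#' Band-pass filter a phase signal
#'
#' Zero-phase (forward-backward) Butterworth band-pass, 50-1500 Hz by
#' default: removes the DC term and slow drift from body sway while
#' keeping the speech fundamental and its low harmonics. The filter is a
#' 2nd-order band-pass section run in both directions (4th-order
#' magnitude response, zero net phase), preserving the temporal alignment
#' that later smoothing and reference comparison rely on.
#'
#' @param signal A `phase_signal` tibble.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Order of the underlying Butterworth section.
#' @return A filtered `phase_signal`.
#' @export
bandpass_filter <- function(signal, low = 50, high = 1500, order = 2) {
  fs <- sampling_rate(signal)
  if (low <= 0 || high <= low) abort("need 0 < low < high")
  if (high >= fs / 2) {
    abort(sprintf("high edge %g Hz must be below Nyquist (%g Hz)", high, fs / 2))
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(bf, signal$phase_rad)
  new_signal_tbl(
    tibble::tibble(time_s = signal$time_s, phase_rad = filtered),
    fs, "phase_signal"
  )
}

#' Voiced-segment extraction by short-term energy
#'
#' Frames the signal, computes per-frame mean-square energy, and marks
#' frames whose energy exceeds `threshold_ratio` times a robust reference
#' (the 95th-percentile frame energy) as voiced. Adjacent voiced frames
#' merge into segments; segments shorter than `minimum_duration_s` are
#' dropped. Because the threshold is a ratio, the segmentation is
#' invariant to overall amplitude scaling. The complement of the voiced
#' segments is returned labelled `"removed"` (silence or unvoiced
#' consonants, which carry no fold vibration).
#'
#' @param signal A `phase_signal` tibble.
#' @param frame_length_s Analysis frame length, s (spans >= 2 pitch
#'   periods at the 50 Hz band edge by default... 25 ms covers >= 2
#'   periods down to 80 Hz and is the conventional speech frame).
#' @param hop_s Frame hop, s.
#' @param threshold_ratio Energy threshold as a fraction of the
#'   95th-percentile frame energy.
#' @param minimum_duration_s Shortest voiced segment kept, s.
#' @return A `segment_table` tibble: `start_s`, `end_s`, `label`
#'   (`"voiced"` or `"removed"`).
#' @export
energy_segments <- function(signal, frame_length_s = 0.025, hop_s = 0.010,
                            threshold_ratio = 0.1, minimum_duration_s = 0.05) {
  fs <- sampling_rate(signal)
  x <- signal$phase_rad %||% signal[[2]]
  n <- length(x)
  L <- max(2L, round(frame_length_s * fs))
  hop <- max(1L, round(hop_s * fs))
  if (L > n) abort("frame_length_s longer than the signal")
  starts <- seq(1L, n - L + 1L, by = hop)
  energy <- vapply(starts, function(s) mean(x[s:(s + L - 1)]^2), numeric(1))
  total_dur <- n / fs

  ref <- quantile(energy, 0.95, names = FALSE)
  voiced_frames <- energy > threshold_ratio * ref & energy > 0

  voiced <- tibble::tibble(start_s = numeric(), end_s = numeric())
  if (any(voiced_frames)) {
    r <- rle(voiced_frames)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    keep <- which(r$values)
    voiced <- tibble::tibble(
      start_s = (starts[starts_i[keep]] - 1) / fs,
      end_s = pmin((starts[ends_i[keep]] - 1 + L) / fs, total_dur)
    )
    voiced <- dplyr::filter(voiced, .data$end_s - .data$start_s >= minimum_duration_s)
  }

  # complement -> "removed" rows, interleaved in time order
  edges <- c(0, as.vector(rbind(voiced$start_s, voiced$end_s)), total_dur)
  rows <- list()
  for (k in seq_len(length(edges) / 2)) {
    a <- edges[2 * k - 1]; b <- edges[2 * k]
    if (b - a > 1e-12) {
      rows[[length(rows) + 1]] <- tibble::tibble(start_s = a, end_s = b,
                                                 label = "removed")
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(voiced, label = "voiced"),
    dplyr::bind_rows(rows)
  )
  out <- dplyr::arrange(out, .data$start_s)
  tibble::new_tibble(out, nrow = nrow(out), class = "segment_table")
}

#' Rows of a segment table labelled voiced
#' @param segments A `segment_table`.
#' @return The voiced rows, in time order.
#' @export
voiced_segments <- function(segments) {
  dplyr::filter(segments, .data$label == "voiced")
}
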