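# Acoustic-side fundamental-frequency references: frame-wise cepstral F0
# (whose mean anchors radar mode selection) and per-period F0 from the
# reciprocal spacing of successive waveform extrema.

#' Cepstrum fundamental-frequency estimates and their mean
#'
#' Frames the audio (Hann window), takes the real cepstrum (inverse
#' transform of the log magnitude spectrum) and looks for a peak in the
#' quefrency band corresponding to \[`f0_min`, `f0_max`\]. A harmonic frame
#' shows a sharp peak at the quefrency equal to its period; frames whose
#' peak prominence (robust z-score of the peak against the in-band
#' cepstrum, `(peak - median) / MAD`) is below `voicing_threshold` are
#' treated as vanishing and excluded. The
#' mean of the surviving values is the scalar reference used to pick the
#' vibration-bearing radar mode.
#'
#' @param audio Real numeric vector (microphone signal).
#' @param sampling_rate Hz.
#' @param frame_length_s,hop_s Analysis frame and hop, s.
#' @param f0_min,f0_max Search band, Hz (`f0_min < f0_max < fs/2`).
#' @param voicing_threshold Minimum cepstral-peak z-score for a frame to
#'   count as voiced.
#' @return A `discrete_f0` tibble (`time_s`, `f0_hz`, surviving frames
#'   only) with attributes `mean_f0_hz`, `n_frames_total`,
#'   `n_frames_voiced`. The mean is exactly `mean(out$f0_hz)`.
#' @export
cepstrum_f0 <- function(audio, sampling_rate, frame_length_s = 0.04,
                        hop_s = 0.01, f0_min = 50, f0_max = 500,
                        voicing_threshold = 6.5) {
  check_finite(audio, "audio")
  if (!(f0_min < f0_max && f0_max < sampling_rate / 2)) {
    abort("need f0_min < f0_max < sampling_rate/2")
  }
  n <- length(audio)
  L <- round(frame_length_s * sampling_rate)
  if (L > n) abort("frame longer than the signal")
  hop <- max(1L, round(hop_s * sampling_rate))
  q_lo <- max(2L, floor(sampling_rate / f0_max))
  q_hi <- ceiling(sampling_rate / f0_min)
  if (q_hi >= L) abort("frame too short to resolve f0_min (increase frame_length_s)")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann

  starts <- seq(1L, n - L + 1L, by = hop)
  times <- numeric(0); values <- numeric(0)
  band <- q_lo:q_hi
  for (s in starts) {
    frame <- audio[s:(s + L - 1)] * win
    if (sum(frame^2) < .Machine$double.eps) next
    logmag <- log(Mod(fft(frame)) + 1e-300)
    cep <- Re(fft(logmag, inverse = TRUE)) / L
    cb <- cep[band + 1L]  # quefrency q lives at index q+1
    pk <- which.max(cb)
    z <- (cb[pk] - median(cb)) / (stats::mad(cb) + .Machine$double.eps)
    if (z >= voicing_threshold) {
      q_star <- band[pk] + parabolic_offset(cb, pk)
      times <- c(times, (s - 1 + L / 2) / sampling_rate)
      values <- c(values, sampling_rate / q_star)
    }
  }
  out <- tibble::new_tibble(
    tibble::tibble(time_s = times, f0_hz = values),
    nrow = length(times), class = "discrete_f0")
  attr(out, "mean_f0_hz") <- if (length(values)) mean(values) else NA_real_
  attr(out, "n_frames_total") <- length(starts)
  attr(out, "n_frames_voiced") <- length(values)
  attr(out, "frame_length_s") <- frame_length_s
  attr(out, "hop_s") <- hop_s
  out
}

#' Mean of a discrete F0 set
#' @param x A `discrete_f0` tibble from [cepstrum_f0()].
#' @return Mean F0 in Hz (`NA` if no voiced frame survived).
#' @export
f0_mean <- function(x) attr(x, "mean_f0_hz", exact = TRUE)

# local maxima above a relative amplitude floor, pruned to a minimum
# spacing (strongest first), with parabolic sub-sample refinement
find_extrema <- function(x, fs, t0, min_rel_amplitude, min_period_s) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  floor_amp <- min_rel_amplitude * max(x)
  cand <- cand[x[cand] > floor_amp & x[cand] > 0]
  if (length(cand) == 0) return(numeric(0))
  # greedy pruning: keep the tallest, drop neighbours within min_period
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- numeric(0)
  min_gap <- min_period_s * fs * 0.8
  for (i in ord) {
    if (all(abs(i - kept) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  t0 + (kept - 1 + vapply(kept, function(i) parabolic_offset(x, i), numeric(1))) / fs
}

#' Per-period F0 from successive same-family waveform extrema
#'
#' Automates the manual labelling procedure used to score radar tracks:
#' successive same-sign extrema t_i of the waveform mark one vibration
#' period each, so `F0 = 1/(t_{i+1} - t_i)`, timestamped at the interval
#' midpoint `(t_i + t_{i+1})/2`. Peaks and valleys are separate extremum
#' families (mixing them would halve the measured periods); extremum
#' locations are refined by parabolic interpolation to reduce the 1/fs
#' quantisation.
#'
#' @param audio Real numeric vector.
#' @param sampling_rate Hz.
#' @param segments Optional `segment_table`; labelling is confined to its
#'   voiced rows (default: the whole signal as one segment).
#' @param families `"peak"`, `"valley"` or both.
#' @param min_rel_amplitude Extrema below this fraction of the segment
#'   maximum are ignored.
#' @param min_period_s Closest admissible extremum spacing, s (rejects
#'   ripple within one period).
#' @return An `f0_track` tibble: `time_s`, `f0_hz`, `source =
#'   "hand_label"`, `segment_id`.
#' @export
hand_label_f0 <- function(audio, sampling_rate, segments = NULL,
                          families = c("peak", "valley"),
                          min_rel_amplitude = 0.3, min_period_s = 1 / 500) {
  families <- match.arg(families, several.ok = TRUE)
  check_finite(audio, "audio")
  n <- length(audio)
  if (is.null(segments)) {
    segs <- tibble::tibble(start_s = 0, end_s = n / sampling_rate)
  } else {
    segs <- voiced_segments(segments)
    if (nrow(segs) == 0) abort("no voiced segments to label")
  }
  rows <- list()
  for (si in seq_len(nrow(segs))) {
    a <- max(1L, floor(segs$start_s[si] * sampling_rate) + 1L)
    b <- min(n, ceiling(segs$end_s[si] * sampling_rate))
    seg <- audio[a:b]
    t0 <- (a - 1) / sampling_rate
    for (fam in families) {
      x <- if (fam == "peak") seg else -seg
      t_ext <- find_extrema(x, sampling_rate, t0, min_rel_amplitude, min_period_s)
      if (length(t_ext) >= 2) {
        dt <- diff(t_ext)
        rows[[length(rows) + 1]] <- tibble::tibble(
          time_s = (t_ext[-length(t_ext)] + t_ext[-1]) / 2,
          f0_hz = 1 / dt,
          source = "hand_label",
          segment_id = si
        )
      }
    }
  }
  out <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows), .data$time_s)
  else tibble::tibble(time_s = numeric(), f0_hz = numeric(),
                      source = character(), segment_id = integer())
  tibble::new_tibble(out, nrow = nrow(out), class = "f0_track")
}
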