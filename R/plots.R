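# ggplot2 views of the main result types.

#' Plot the decomposed modes of a VMD result
#'
#' One facet per mode, centre frequency in the strip label.
#'
#' @param object A `vmd_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vmd_result <- function(object, ...) {
  df <- tidy(object)
  labs <- sprintf("%s (%.4g Hz)", colnames(object$modes),
                  object$center_frequencies_hz)
  names(labs) <- colnames(object$modes)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~mode, ncol = 1, scales = "free_y",
                        labeller = ggplot2::labeller(mode = labs)) +
    ggplot2::labs(x = "time (s)", y = "mode amplitude",
                  title = "Variational mode decomposition")
}

#' Plot an F0 track
#'
#' Continuous sources (radar) draw as lines, discrete references
#' (hand-label, cepstrum) as points.
#'
#' @param object An `f0_track` tibble.
#' @param ... Additional `f0_track`s to overlay (e.g. a reference).
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.f0_track <- function(object, ...) {
  extra <- list(...)
  df <- dplyr::bind_rows(c(list(tibble::as_tibble(object)),
                           lapply(extra, tibble::as_tibble)))
  discrete <- df$source %in% c("hand_label", "cepstrum")
  p <- ggplot2::ggplot(mapping = ggplot2::aes(.data$time_s, .data$f0_hz,
                                              colour = .data$source))
  if (any(!discrete)) {
    p <- p + ggplot2::geom_line(
      data = df[!discrete, ],
      mapping = ggplot2::aes(group = interaction(.data$source, .data$segment_id)),
      na.rm = TRUE)
  }
  if (any(discrete)) {
    p <- p + ggplot2::geom_point(data = df[discrete, ], shape = 4, na.rm = TRUE)
  }
  p + ggplot2::labs(x = "time (s)", y = "fundamental frequency (Hz)",
                    title = "Time-varying vocal-fold vibration frequency")
}

#' Plot an evaluation report's per-point deviations
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$time_s, 100 * .data$relative_deviation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference time (s)", y = "relative deviation (%)",
                  title = sprintf("Track vs reference: e = %.2f%%, |e| = %.2f%%",
                                  object$e_signed_pct, object$e_abs_pct))
}

#' Plot a phase signal with its voiced segments shaded
#'
#' @param object A `phase_signal`.
#' @param segments Optional `segment_table` to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phase_signal <- function(object, segments = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time_s, .data$phase_rad)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "demodulated phase (rad)",
                  title = "Radar baseband phase")
  if (!is.null(segments)) {
    vs <- voiced_segments(segments)
    if (nrow(vs)) {
      p <- p + ggplot2::geom_rect(
        data = vs, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf),
        fill = "steelblue", alpha = 0.15)
    }
  }
  p
}
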