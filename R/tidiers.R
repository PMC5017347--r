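# broom-style tidiers for fitted/derived objects.

#' Tidy a VMD result into a long tibble
#'
#' @param x A `vmd_result`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `mode` (factor mode1..modeK), `value`.
#' @exportS3Method generics::tidy
tidy.vmd_result <- function(x, ...) {
  n <- nrow(x$modes)
  df <- tibble::as_tibble(x$modes)
  df$time_s <- (seq_len(n) - 1) / x$sampling_rate
  tidyr::pivot_longer(df, -"time_s", names_to = "mode", values_to = "value")
}

#' One-row summary of a VMD result
#'
#' @param x A `vmd_result`.
#' @param ... Unused.
#' @return Tibble with mode count, sorted centre frequencies, iteration
#'   count, convergence flag, final convergence metric and residual norm.
#' @exportS3Method generics::glance
glance.vmd_result <- function(x, ...) {
  tibble::tibble(
    n_modes = ncol(x$modes),
    center_frequencies_hz = paste(signif(sort(x$center_frequencies_hz), 6),
                                  collapse = ", "),
    iterations = x$iterations,
    converged = x$converged,
    final_change = utils::tail(x$convergence_history, 1),
    residual_l2 = sqrt(sum(x$residual^2))
  )
}

#' Per-point deviations of an evaluation report
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-point tibble (`time_s`, reference and radar F0,
#'   `relative_deviation`).
#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) x$points

#' One-row summary of an evaluation report
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(e_signed_pct = x$e_signed_pct, e_abs_pct = x$e_abs_pct,
                 n_used = x$n_used, n_excluded = x$n_excluded,
                 duration_s = x$duration_s)
}

#' Tidy a pipeline run into its F0 track
#' @param x A `radar_track_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.radar_track_result <- function(x, ...) tibble::as_tibble(x$track)

#' Per-segment summary of a pipeline run
#' @param x A `radar_track_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.radar_track_result <- function(x, ...) {
  if (nrow(x$log) == 0) return(tibble::tibble())
  dplyr::select(x$log, "segment_id", "start_s", "end_s", "reference_source",
                "reference_mean_hz", "selected_mode", "dominant_frequency_hz",
                "vmd_iterations", "vmd_converged")
}
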