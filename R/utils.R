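# Small signal-processing primitives shared across modules.

#' Sampling rate of a vocalradar signal table
#'
#' Signal tibbles produced by this package (vibration tracks, quadrature
#' recordings, phase signals) carry their sampling rate as an attribute;
#' this accessor retrieves it.
#'
#' @param x A signal tibble created by vocalradar.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  fs <- attr(x, "sampling_rate", exact = TRUE)
  if (is.null(fs)) {
    # fall back to the time grid if the attribute was stripped by wrangling
    if (is.data.frame(x) && "time_s" %in% names(x) && nrow(x) > 1) {
      fs <- 1 / median(diff(x$time_s))
    } else {
      abort("cannot determine sampling rate: no attribute and no time grid")
    }
  }
  fs
}

new_signal_tbl <- function(df, sampling_rate, subclass) {
  out <- tibble::new_tibble(df, nrow = nrow(df), class = c(subclass, "vr_signal"))
  attr(out, "sampling_rate") <- sampling_rate
  out
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("%s must be finite (found NA/NaN/Inf)", what))
  }
  invisible(x)
}

# Phase unwrapping: remove 2*pi jumps between adjacent samples.
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  cumsum(c(p[1], d - 2 * pi * round(d / (2 * pi))))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Zeroes the negative half of the spectrum (doubling the positive half,
#' keeping DC and Nyquist untouched) and inverse-transforms, yielding the
#' complex analytic signal whose argument is the instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  check_finite(x, "signal")
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# NA-aware centred rectangular moving average with edge shrinkage.
rolling_mean_na <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  zoo::rollapply(x, width, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, partial = TRUE, align = "center")
}

# Parabolic interpolation of a discrete extremum at index i of y;
# returns fractional index offset in (-0.5, 0.5).
parabolic_offset <- function(y, i) {
  if (i <= 1 || i >= length(y)) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}
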