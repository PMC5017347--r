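test_that("a single pure tone is recovered as one narrow mode", {
  fs <- 1000
  x <- make_tone(100, fs, 1)
  res <- vmd_decompose(x, vmd_config(n_modes = 1), sampling_rate = fs)
  expect_true(res$converged)
  bin <- fs / length(x)
  expect_lte(abs(res$center_frequencies_hz - 100), bin)
  interior <- 101:900
  rel_l2 <- sqrt(sum((res$modes[interior, 1] - x[interior])^2) /
                   sum(x[interior]^2))
  expect_lt(rel_l2, 1e-3)
})

test_that("two well-separated tones split into two correctly centred modes", {
  fs <- 8000
  x <- make_tone(100, fs, 2) + make_tone(300, fs, 2)
  res <- vmd_decompose(x, vmd_config(), sampling_rate = fs)
  expect_true(res$converged)
  bin <- fs / length(x)
  centres <- sort(res$center_frequencies_hz)
  expect_lte(abs(centres[1] - 100), bin)
  expect_lte(abs(centres[2] - 300), bin)
  # each mode's spectral peak matches its centre frequency
  for (k in 1:2) {
    pk <- mode_peak_frequency(res$modes[, k], fs)
    expect_lte(abs(pk - res$center_frequencies_hz[k]), 2 * bin)
  }
})

test_that("the zero signal converges immediately to zero modes", {
  res <- vmd_decompose(rep(0, 256), vmd_config(), sampling_rate = 1000)
  expect_true(all(res$modes == 0))
  expect_identical(res$iterations, 1L)
  expect_true(res$converged)
})

test_that("centre frequency of a pure tone is a fixed point across init schemes", {
  fs <- 2000
  x <- make_tone(170, fs, 1)
  bin <- fs / length(x)
  for (scheme in c("uniform", "zero")) {
    res <- vmd_decompose(x, vmd_config(n_modes = 1, init_scheme = scheme),
                         sampling_rate = fs)
    expect_lte(abs(res$center_frequencies_hz - 170), bin)
  }
  for (s in 1:3) {
    res <- vmd_decompose(x, vmd_config(n_modes = 1, init_scheme = "random"),
                         sampling_rate = fs, seed = s)
    expect_lte(abs(res$center_frequencies_hz - 170), bin)
  }
})

test_that("mode set is invariant to initialisation order for separated tones", {
  fs <- 8000
  x <- make_tone(120, fs, 1) + make_tone(500, fs, 1)
  bin <- fs / length(x)
  ref <- sort(vmd_decompose(x, vmd_config(), sampling_rate = fs)$center_frequencies_hz)
  for (s in 1:3) {
    res <- vmd_decompose(x, vmd_config(init_scheme = "random"),
                         sampling_rate = fs, seed = s)
    expect_equal(sort(res$center_frequencies_hz), ref, tolerance = 2 * bin / 100)
  }
})

test_that("larger alpha narrows the modes", {
  fs <- 8000
  withr::with_seed(5, {
    x <- make_tone(150, fs, 1) + make_tone(450, fs, 1) +
      0.05 * stats::rnorm(fs)
  })
  # RMS spectral bandwidth around the power centroid
  rms_width <- function(mode) {
    p <- Mod(stats::fft(mode))[seq_len(fs / 2)]^2
    f <- (seq_len(fs / 2) - 1) * fs / length(mode)
    mu <- sum(f * p) / sum(p)
    sqrt(sum((f - mu)^2 * p) / sum(p))
  }
  w_small <- vmd_decompose(x, vmd_config(alpha = 100), sampling_rate = fs)
  w_large <- vmd_decompose(x, vmd_config(alpha = 5000), sampling_rate = fs)
  expect_lt(mean(apply(w_large$modes, 2, rms_width)),
            mean(apply(w_small$modes, 2, rms_width)))
})

test_that("centre frequencies match the FFT peak-pick oracle on random two-tone signals", {
  fs <- 4000
  bin <- fs / fs  # 1 s signals
  for (s in 1:10) {
    withr::with_seed(s, {
      f_lo <- stats::runif(1, 80, 250)
      f_hi <- stats::runif(1, 600, 1500)
      x <- make_tone(f_lo, fs, 1) + make_tone(f_hi, fs, 1)
    })
    res <- vmd_decompose(x, vmd_config(), sampling_rate = fs)
    oracle <- fft_peaks_hz(x, fs, n = 2, min_sep_hz = 100)
    expect_true(res$converged, info = sprintf("seed %d", s))
    expect_lte(max(abs(sort(res$center_frequencies_hz) - oracle)), 2 * bin)
  }
})

test_that("reconstruction: modes plus residual return the input", {
  fs <- 4000
  withr::with_seed(11, x <- make_tone(120, fs, 1) + make_tone(700, fs, 1) +
                     0.1 * stats::rnorm(fs))
  res <- vmd_decompose(x, vmd_config(), sampling_rate = fs)
  expect_equal(rowSums(res$modes) + res$residual, x, tolerance = 1e-12)
  # when the modes can cover the content (two clean tones, K = 2), the
  # dual ascent still satisfies the reconstruction constraint tightly;
  # with tau = 0 the noisy input above leaves the noise in the residual
  x2 <- make_tone(130.27, fs, 1) + make_tone(707.13, fs, 1)
  interior <- (fs / 4):(3 * fs / 4)
  rms_resid <- function(r) sqrt(mean(r$residual[interior]^2))
  r_tau <- vmd_decompose(x2, vmd_config(tau = 0.5), sampling_rate = fs)
  expect_true(r_tau$converged)
  expect_lt(rms_resid(r_tau), 0.01)
  expect_gt(rms_resid(res), 0.05)  # K = 2 cannot absorb the broadband noise
})

test_that("non-convergence is flagged, never silent", {
  fs <- 2000
  x <- make_tone(100, fs, 1) + make_tone(400, fs, 1)
  res <- vmd_decompose(x, vmd_config(max_iterations = 2), sampling_rate = fs)
  expect_false(res$converged)
  expect_identical(res$iterations, 2L)
  expect_identical(length(res$convergence_history), 2L)
})

test_that("invalid inputs are rejected", {
  expect_error(vmd_decompose(c(1, NA, 3), vmd_config()), "finite")
  expect_error(vmd_decompose(rep(1, 8), vmd_config()), "16")
  expect_error(vmd_config(alpha = -1))
  expect_error(vmd_config(n_modes = 0))
})

test_that("convergence history decreases below tol under the default settings", {
  fs <- 8000
  fixtures <- list(
    two_tone = make_tone(100, fs, 1) + make_tone(300, fs, 1),
    tone_noise = withr::with_seed(3, make_tone(170, fs, 1) + 0.1 * stats::rnorm(fs)),
    chirp = make_chirp(150, 250, fs, 1)
  )
  for (nm in names(fixtures)) {
    res <- vmd_decompose(fixtures[[nm]], vmd_config(), sampling_rate = fs)
    expect_true(res$converged, info = nm)
    expect_lte(res$iterations, 500L)
    h <- res$convergence_history
    expect_true(all(h[-length(h)] >= res$config$tol), info = nm)
    expect_lt(h[length(h)], res$config$tol)
  }
})

test_that("spectral peak picking matches a brute-force oracle", {
  fs <- 8000
  expect_equal(mode_peak_frequency(make_tone(170, fs, 1), fs), 170)
  two <- 2 * make_tone(120, fs, 1) + make_tone(360, fs, 1)
  expect_equal(mode_peak_frequency(two, fs), 120)
  withr::with_seed(9, noise <- stats::rnorm(4096))
  expect_identical(mode_peak_frequency(noise, fs), fft_peak_hz(noise, fs))
  expect_error(mode_peak_frequency(rep(0, 64), fs),
               class = "vocalradar_zero_mode")
})

test_that("vmd results tidy and summarise cleanly", {
  fs <- 2000
  res <- vmd_decompose(make_tone(100, fs, 0.5) + make_tone(400, fs, 0.5),
                       vmd_config(), sampling_rate = fs)
  td <- tidy(res)
  expect_named(td, c("time_s", "mode", "value"))
  expect_identical(nrow(td), 2L * nrow(res$modes))
  g <- glance(res)
  expect_identical(g$n_modes, 2L)
  expect_true(g$converged)
})
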