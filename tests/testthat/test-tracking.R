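# assemble a vmd_result by hand from known mode series
fake_vmd <- function(..., fs = 8000) {
  modes <- do.call(cbind, list(...))
  colnames(modes) <- paste0("mode", seq_len(ncol(modes)))
  structure(
    list(modes = modes, center_frequencies_hz = rep(NA_real_, ncol(modes)),
         iterations = 1L, converged = TRUE, convergence_history = 0,
         residual = rep(0, nrow(modes)), sampling_rate = fs,
         config = vmd_config(n_modes = ncol(modes))),
    class = "vmd_result")
}

test_that("mode selection picks the mode nearest the reference mean", {
  fs <- 8000
  res <- fake_vmd(make_tone(170, fs, 1), make_tone(900, fs, 1), fs = fs)
  sel <- select_vibration_mode(res, 165)
  expect_identical(as.integer(sel), 1L)
  expect_equal(attr(sel, "peak_frequencies_hz"), c(170, 900))
  expect_equal(attr(sel, "distances_hz"), c(5, 735))

  sel2 <- select_vibration_mode(res, 880)
  expect_identical(as.integer(sel2), 2L)
})

test_that("a single mode is selected unconditionally", {
  res <- fake_vmd(make_tone(300, 8000, 1), fs = 8000)
  expect_identical(as.integer(select_vibration_mode(res, 50)), 1L)
})

test_that("equidistant peaks break the tie toward the lower index, audibly", {
  fs <- 8000
  res <- fake_vmd(make_tone(100, fs, 1), make_tone(300, fs, 1), fs = fs)
  expect_message(sel <- select_vibration_mode(res, 200), "tie")
  expect_identical(as.integer(sel), 1L)
  expect_true(attr(sel, "tie"))
})

test_that("mode selection rejects degenerate inputs", {
  res <- fake_vmd(rep(0, 1000), rep(0, 1000), fs = 8000)
  expect_error(select_vibration_mode(res, 170), class = "vocalradar_zero_mode")
  good <- fake_vmd(make_tone(170, 8000, 1), fs = 8000)
  expect_error(select_vibration_mode(good, -5), "positive")
})

test_that("instantaneous frequency of a pure tone is flat at the tone", {
  fs <- 8000
  tr <- instantaneous_frequency(make_tone(170, fs, 1), fs)
  interior <- tr$f0_hz[400:(fs - 400)]
  expect_true(all(abs(interior - 170) < 0.5))
})

test_that("instantaneous frequency follows a linear chirp", {
  fs <- 8000
  tr <- instantaneous_frequency(make_chirp(100, 200, fs, 1), fs)
  at_mid <- tr$f0_hz[which.min(abs(tr$time_s - 0.5))]
  expect_lt(abs(at_mid - 150), 2)
})

test_that("amplitude modulation does not leak into the frequency estimate", {
  fs <- 8000
  t <- (0:(fs - 1)) / fs
  env <- 0.05 + 0.95 * (0.5 - 0.5 * cos(2 * pi * t))  # slow AM dip to 5%
  x <- env * cos(2 * pi * 170 * t)
  tr <- instantaneous_frequency(x, fs)
  z_amp <- Mod(analytic_signal(x))
  ok <- which(z_amp > 0.1 * max(z_amp))
  ok <- ok[ok > 200 & ok < fs - 200]
  expect_true(all(abs(tr$f0_hz[ok] - 170) < 3, na.rm = TRUE))
  # masked samples are NA, not wild numbers
  expect_true(anyNA(tr$f0_hz) || all(z_amp >= 0.1 * max(z_amp)))
})

test_that("smoothing preserves constants and averages out alternating jitter", {
  fs <- 1000
  n <- 500
  const <- tibble::tibble(time_s = (0:(n - 1)) / fs, f0_hz = rep(170, n),
                          source = "radar", segment_id = 1L)
  out <- smooth_frequency(const, dominant_period_s = 1 / 170)
  expect_equal(out$f0_hz, const$f0_hz)

  jitter <- const
  jitter$f0_hz <- 170 + 10 * rep_len(c(1, -1), n)
  sm <- smooth_frequency(jitter, dominant_period_s = 1 / 170)
  expect_true(all(abs(sm$f0_hz - 170) < 1))
})

test_that("smoothing leaves a linear ramp unchanged away from the edges", {
  fs <- 1000
  n <- 500
  ramp <- tibble::tibble(time_s = (0:(n - 1)) / fs,
                         f0_hz = seq(150, 250, length.out = n),
                         source = "radar", segment_id = 1L)
  w <- round(3 * (1 / 170) * fs)  # window samples
  sm <- smooth_frequency(ramp, dominant_period_s = 1 / 170)
  interior <- (w + 1):(n - w)
  expect_equal(sm$f0_hz[interior], ramp$f0_hz[interior], tolerance = 1e-9)
})

test_that("smoothing commutes with adding a constant", {
  fs <- 1000
  withr::with_seed(4, f0 <- 180 + 5 * stats::rnorm(400))
  tr <- tibble::tibble(time_s = (0:399) / fs, f0_hz = f0,
                       source = "radar", segment_id = 1L)
  plus <- tr; plus$f0_hz <- plus$f0_hz + 25
  a <- smooth_frequency(plus, 1 / 170)$f0_hz
  b <- smooth_frequency(tr, 1 / 170)$f0_hz + 25
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("an over-long smoothing window falls back to the segment mean with a warning", {
  tr <- tibble::tibble(time_s = (0:49) / 1000, f0_hz = seq(100, 200, length.out = 50),
                       source = "radar", segment_id = 1L)
  expect_warning(sm <- smooth_frequency(tr, dominant_period_s = 1), "mean")
  expect_equal(sm$f0_hz, rep(mean(tr$f0_hz), 50))
})

test_that("relative error arithmetic on constant-multiple tracks is exact", {
  ref <- tibble::tibble(time_s = seq(0.1, 0.9, by = 0.1), f0_hz = rep(200, 9))
  radar <- tibble::tibble(time_s = seq(0, 1, by = 0.001), f0_hz = 200,
                          source = "radar", segment_id = 1L)
  expect_equal(relative_error(radar, ref)$e_signed_pct, 0)

  radar105 <- radar; radar105$f0_hz <- 1.05 * radar105$f0_hz
  rep105 <- relative_error(radar105, ref)
  expect_equal(rep105$e_signed_pct, 5, tolerance = 1e-12)
  expect_equal(rep105$e_abs_pct, 5, tolerance = 1e-12)

  for (c_mult in c(0.8, 1.3)) {
    radc <- radar; radc$f0_hz <- c_mult * radc$f0_hz
    expect_equal(relative_error(radc, ref)$e_signed_pct, (c_mult - 1) * 100,
                 tolerance = 1e-12)
  }
})

test_that("symmetric deviations cancel in the signed mean but not the absolute one", {
  ref <- tibble::tibble(time_s = c(0.2, 0.4), f0_hz = c(200, 200))
  radar <- tibble::tibble(time_s = c(0.2, 0.4), f0_hz = c(210, 190),
                          source = "radar", segment_id = 1L)
  rep <- relative_error(radar, ref)
  expect_equal(rep$e_signed_pct, 0, tolerance = 1e-12)
  expect_equal(rep$e_abs_pct, 5, tolerance = 1e-12)
})

test_that("out-of-coverage reference points are excluded and counted", {
  ref <- tibble::tibble(time_s = c(0.5, 0.6, 5), f0_hz = c(200, 200, 200))
  radar <- tibble::tibble(time_s = seq(0, 1, by = 0.01), f0_hz = 200,
                          source = "radar", segment_id = 1L)
  rep <- relative_error(radar, ref)
  expect_identical(rep$n_used, 2L)
  expect_identical(rep$n_excluded, 1L)
  disjoint <- tibble::tibble(time_s = c(10, 11), f0_hz = c(200, 200))
  expect_error(relative_error(radar, disjoint), "disjoint")
})
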