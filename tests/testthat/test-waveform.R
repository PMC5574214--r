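test_that("generator is deterministic in the seed", {
  a <- synth_doppler_series(seed = 11)
  b <- synth_doppler_series(seed = 11)
  c <- synth_doppler_series(seed = 12)
  expect_identical(a$v, b$v)
  expect_false(identical(a$v, c$v))
})

test_that("generator envelope matches the requested velocities", {
  ser <- synth_doppler_series(v_peak = 90, v_min = 33, jitter = 0, noise_sd = 0,
                              seed = 1)
  expect_equal(max(ser$v), 90, tolerance = 0.02)
  # v_min is the end-diastolic (beat-foot) value; with period 0.85 and
  # fs = 200 the feet fall on sample points (0.85 * 200 = 170)
  expect_equal(ser$v[1 + 170 * (0:11)], rep(33, 12))
  # the interpolated envelope may undershoot v_min slightly between the
  # landmark points but stays in a physiological band
  expect_gt(min(ser$v), 25)
  expect_lte(min(ser$v), 33)
  # with jitter and noise the envelope stays within a physiological band
  ser2 <- synth_doppler_series(seed = 1)
  expect_gt(min(ser2$v), 20)
  expect_lt(max(ser2$v), 110)
})

test_that("generator produces the requested number of beats and duration", {
  ser <- synth_doppler_series(period = 0.85, n_beats = 12, jitter = 0,
                              noise_sd = 0, seed = 1)
  meta <- attr(ser, "meta")
  expect_equal(length(meta$feet), 13L)
  expect_equal(max(ser$t), 12 * 0.85, tolerance = 0.01)
  # one systolic peak per beat
  pk <- sum(diff(sign(diff(ser$v))) == -2 & ser$v[2:(nrow(ser) - 1)] > 70)
  expect_equal(pk, 12L)
})

test_that("generator rejects invalid parameters", {
  expect_error(synth_doppler_series(period = -1), "period")
  expect_error(synth_doppler_series(n_beats = 0), "n_beats")
  expect_error(synth_doppler_series(jitter = -0.1), "jitter")
  expect_error(synth_doppler_series(v_peak = 30, v_min = 33), "v_peak")
})

test_that("Fourier peak averaging recovers a clean beat from noisy data", {
  # with zero jitter/noise the average must reproduce the single-beat shape
  ser <- synth_doppler_series(jitter = 0, noise_sd = 0, seed = 1)
  wf <- fourier_average_peaks(ser, n_peaks = 10, period = 0.85)
  expect_s3_class(wf, "ipad_waveform")
  expect_equal(nrow(wf), 1024L)
  expect_equal(max(wf$v), 90, tolerance = 0.02)
  expect_equal(min(wf$v), min(ser$v), tolerance = 0.02)
  # with noise, averaging suppresses it. Noisy feet shift the detected beat
  # start by up to a sample, so compare up to a circular phase shift: the
  # best-aligned residual must be at the averaged-noise level, far below the
  # per-sample noise near the steep systolic upstroke
  sern <- synth_doppler_series(jitter = 0, noise_sd = 1, seed = 2)
  wfn <- fourier_average_peaks(sern, n_peaks = 10, period = 0.85)
  aligned <- vapply(-20:20, function(s) {
    stats::median(abs(wfn$v - wf$v[1 + (seq_len(1024) - 1 + s) %% 1024]))
  }, 1)
  expect_lt(min(aligned), 0.6)
})

test_that("averaging errors when too few beats are present", {
  ser <- synth_doppler_series(n_beats = 4, seed = 1)
  expect_error(fourier_average_peaks(ser, n_peaks = 10), "insufficient data")
})

test_that("velocity-to-flux conversion is exact unit arithmetic", {
  wf <- tibble::tibble(t = c(0, 0.425), v = c(50, 50))
  attr(wf, "period") <- 0.85
  class(wf) <- c("ipad_waveform", class(wf))
  qf <- velocity_to_flux(wf, lumen_radius = 0.14)
  # 50 cm/s * pi * 0.14^2 cm^2  [DERIVED: direct arithmetic]
  expect_equal(qf$q, c(3.078760801, 3.078760801), tolerance = 1e-9)
  expect_identical(attr(qf, "kind"), "flux")
  expect_error(velocity_to_flux(wf, lumen_radius = -1), "lumen_radius")
  expect_error(velocity_to_flux(wf, 0.14, profile_factor = 0), "profile_factor")
})

test_that("waveform evaluation wraps periodically", {
  wf <- fourier_average_peaks(synth_doppler_series(seed = 1))
  t0 <- c(0.1, 0.3)
  expect_equal(evaluate_waveform(wf, t0), evaluate_waveform(wf, t0 + 0.85),
               tolerance = 1e-12)
})

test_that("default inlet flux lies in the physiological MCA range", {
  cfg <- ipad_config()
  wf <- inlet_flux_waveform(cfg)
  # bounds follow from the frozen velocity calibration: the peak systolic
  # flux is v_peak * pi * r^2 = 90 * pi * 0.14^2 ~ 5.54 cm^3/s (small spline
  # overshoot allowed) and the diastolic floor stays above ~25 cm/s
  expect_gt(min(wf$q), 1.4)
  expect_lt(max(wf$q), 5.8)
  # time-mean MCA volumetric flow, literature range
  expect_gt(mean(wf$q), 2.0)
  expect_lt(mean(wf$q), 3.5)
})

test_that("waveform fixtures round-trip through CSV + JSON sidecar", {
  wf <- velocity_to_flux(fourier_average_peaks(synth_doppler_series(seed = 3)),
                         lumen_radius = 0.14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(wf, path)
  back <- read_waveform(path)
  expect_equal(back$q, wf$q, tolerance = 1e-12)
  expect_equal(attr(back, "period"), 0.85)
  expect_identical(attr(back, "kind"), "flux")
})
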