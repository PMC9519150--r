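test_that("tone bursts have the documented length and Nyquist guard", {
  b <- make_tone_burst(60e3, cycles = 4, sample_rate = 512e3)
  expect_equal(attr(b, "burst_samples"), 34)    # round(4/60e3 * 512e3) = 34
  expect_equal(attr(b, "exact_duration"), 4 / 60e3)
  z <- make_tone_burst(40e3, amplitude = 0)
  expect_true(all(z$samples == 0))
  expect_error(make_tone_burst(300e3, sample_rate = 512e3), "Nyquist")
})

test_that("test frequencies map to their recording bands", {
  expect_equal(bandpass_for(23e3), c(10e3, 30e3))
  expect_equal(bandpass_for(40e3), c(30e3, 50e3))
  expect_equal(bandpass_for(60e3), c(50e3, 70e3))
  expect_warning(b <- bandpass_for(80e3), "No standard band")
  expect_equal(b, c(70e3, 90e3))
})

test_that("band-pass filtering is amplitude-preserving in band and steep out", {
  fs <- 512e3
  tt <- seq(0, 5e-3, by = 1 / fs)
  band <- bandpass_for(40e3)
  in_band <- apply_bandpass(trace(sin(2 * pi * 40e3 * tt), fs), band)
  mid <- seq(800, 1800)
  expect_equal(max(abs(in_band$samples[mid])), 1, tolerance = 0.01)
  out_band <- apply_bandpass(trace(sin(2 * pi * 100e3 * tt), fs), band)
  expect_lt(20 * log10(max(abs(out_band$samples[mid]))), -40)
  dc <- apply_bandpass(trace(rep(1, 2048), fs), band)
  expect_lt(max(abs(dc$samples[500:1500])), 1e-3)
  expect_error(apply_bandpass(trace(tt, fs), c(0, 1e3)), "Nyquist|band")
})

test_that("second-cycle arrival lands one period after a constructed onset", {
  b <- make_tone_burst(40e3, onset = 1e-3, duration = 3e-3)
  m <- second_cycle_metrics(b, 40e3)
  expect_true(m$detected)
  expect_lt(abs(m$arrival_time - (1e-3 + 1 / 40e3)), 1 / 512e3)
  expect_equal(m$displacement, 1, tolerance = 0.01)
})

test_that("arrival extraction is shift-equivariant and scale-invariant", {
  b1 <- make_tone_burst(40e3, onset = 1e-3, duration = 3e-3)
  b2 <- make_tone_burst(40e3, onset = 1.2e-3, duration = 3e-3)
  m1 <- second_cycle_metrics(b1, 40e3)
  m2 <- second_cycle_metrics(b2, 40e3)
  expect_lt(abs((m2$arrival_time - m1$arrival_time) - 0.2e-3), 1 / 512e3)
  b3 <- b1; b3$samples <- 7.3 * b3$samples
  m3 <- second_cycle_metrics(b3, 40e3)
  expect_equal(m3$arrival_time, m1$arrival_time)
  expect_equal(m3$displacement, 7.3 * m1$displacement)
})

test_that("pure noise yields an explicit no-detection", {
  withr::with_seed(11, {
    nz <- trace(rnorm(4096), 512e3)
    m <- second_cycle_metrics(nz, 40e3)
    expect_false(m$detected)
    expect_true(is.na(m$arrival_time))
  })
})

test_that("phase formula: degrees = 360 f dt, exact on whole cycles", {
  expect_equal(phase_difference_deg(60e3, 0.25 / 60e3), 90)
  expect_equal(phase_difference_deg(60e3, 0), 0)
  expect_equal(phase_difference_deg(23e3, 9.77e-6), 80.9, tolerance = 0.01)
  for (n in 1:5) {
    expect_equal(phase_difference_deg(40e3, n / 40e3), 360 * n)
  }
  expect_equal(phase_difference_deg(40e3, 1.5 / 40e3, wrap = TRUE), 180)
  expect_equal(phase_difference_deg(40e3, -0.25 / 40e3), 90)  # absolute value
})

test_that("point zero recovers an injected symmetry axis", {
  cfg <- generator_config(seed = 5, noise_sd = 0.02)
  sweep0 <- gen_angle_sweep(cfg, 60e3, "intact", axis_deg = 0)
  expect_equal(find_point_zero(sweep0, 60e3)$point_zero_deg, 0)
  sweep3 <- gen_angle_sweep(cfg, 60e3, "intact", axis_deg = 3)
  expect_equal(find_point_zero(sweep3, 60e3)$point_zero_deg, 3)
})

test_that("point zero fails loudly on an all-noise sweep", {
  cfg <- generator_config(seed = 6)
  sweep <- gen_angle_sweep(cfg, 60e3, "intact")
  sweep$trace <- lapply(seq_len(nrow(sweep)), function(i) {
    withr::with_seed(i, trace(rnorm(1024), 512e3))
  })
  expect_error(find_point_zero(sweep, 60e3), ">= 3 angles")
})

test_that("chirp transfer is flat for identical signals and finds resonances", {
  fs <- 512e3
  withr::with_seed(2, y <- rnorm(fs * 0.05))
  a <- trace(y, fs); b <- trace(y, fs)
  g <- chirp_transfer(a, b)
  expect_true(all(abs(g$gain_db) < 1e-9))
  cfg <- generator_config(seed = 7)
  ch <- gen_chirp_response(cfg, 107.84e3, q_factor = 30)
  spec <- chirp_transfer(ch$response, ch$stimulus)
  pk <- resonance_peak(spec, c(80e3, 120e3))
  expect_true(pk$found && !pk$boundary)
  expect_lt(abs(pk$f_peak - ch$truth$f_peak_analytic), attr(spec, "bin_hz"))
  # the recovered peak gain should be close to the SDOF magnitude peak
  expect_equal(pk$gain_peak, 20 * log10(30), tolerance = 1)
  short <- trace(rnorm(100), fs)
  expect_error(chirp_transfer(short, trace(rnorm(200), fs)), "lengths differ")
})

test_that("resonance peak handles boundaries, ties and flat spectra", {
  f <- seq(1, 100) * 1e3
  mono <- tibble::tibble(frequency = f, gain_db = seq_along(f) * 0.1)
  pk <- resonance_peak(mono)
  expect_true(pk$boundary)
  flat <- tibble::tibble(frequency = f, gain_db = rep(1, length(f)))
  expect_false(resonance_peak(flat)$found)
  two <- tibble::tibble(frequency = f, gain_db = c(rep(0, 20), 5, rep(0, 50), 5, rep(0, 28)))
  pk2 <- resonance_peak(two)
  expect_true(pk2$tie)
  expect_equal(pk2$f_peak, f[21])
  expect_error(resonance_peak(flat, c(200e3, 300e3)), "intersect")
})

test_that("peak interpolation is sweep-step independent", {
  f0 <- 107.3e3
  coarse <- seq(90e3, 125e3, by = 5e3)
  fine <- seq(90e3, 125e3, by = 1e3)
  gain <- function(f) 20 * log10(sdof_magnitude(f, f0, 25))
  pk_c <- resonance_peak(tibble::tibble(frequency = coarse, gain_db = gain(coarse)))
  pk_f <- resonance_peak(tibble::tibble(frequency = fine, gain_db = gain(fine)))
  expect_equal(pk_c$f_peak, f0, tolerance = 0.01)
  expect_equal(pk_f$f_peak, f0, tolerance = 0.002)
})

test_that("print-scale frequency conversion matches the scaled stimuli", {
  expect_equal(round(scale_frequency(60, 11.43), 2), 5.25)
  expect_equal(round(scale_frequency(23, 11.43), 2), 2.01)
  expect_equal(round(scale_frequency(40, 11.43), 2), 3.50)
  expect_equal(scale_frequency(60e3, 1), 60e3)
  expect_error(scale_frequency(60e3, 0), "positive")
})
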