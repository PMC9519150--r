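test_that("generators are pure functions of seed and arguments", {
  cfg <- generator_config(seed = 42)
  expect_identical(gen_morphometry(cfg, 8), gen_morphometry(cfg, 8))
  expect_identical(gen_threshold_matrix(cfg), gen_threshold_matrix(cfg))
  s1 <- gen_angle_sweep(cfg, 40e3, "intact")
  s2 <- gen_angle_sweep(cfg, 40e3, "intact")
  expect_identical(s1$trace[[5]]$samples, s2$trace[[5]]$samples)
  n1 <- gen_neural_trace(cfg)
  n2 <- gen_neural_trace(cfg)
  expect_identical(n1$trace$samples, n2$trace$samples)
  # different seeds differ
  cfg2 <- generator_config(seed = 43)
  expect_false(identical(gen_morphometry(cfg, 8)$slit_area_mm2,
                         gen_morphometry(cfg2, 8)$slit_area_mm2))
  # generators leave the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_morphometry(cfg, 4)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("morphometry draws concentrate on the configured means", {
  cfg0 <- generator_config(seed = 1,
                           morphometry_sds = list(slit_area_mm2 = 0,
                                                  cavity_volume_mm3 = 0))
  m0 <- gen_morphometry(cfg0, 5)
  expect_true(all(m0$slit_area_mm2 == 0.16))
  expect_true(all(m0$cavity_volume_mm3 == 0.14))
  cfg <- generator_config(seed = 2)
  m <- gen_morphometry(cfg, 400)
  se <- 0.01 / sqrt(400)
  expect_lt(abs(mean(m$slit_area_mm2) - 0.16), 3 * se)
  expect_lt(abs(mean(m$cavity_volume_mm3) - 0.14), 3 * se)
  expect_true(all(m$slit_area_mm2 > 0))
})

test_that("angle sweeps carry recoverable ground-truth delays", {
  cfg <- generator_config(seed = 3, noise_sd = 0)
  sweep <- gen_angle_sweep(cfg, 60e3, "intact")
  truth <- attr(sweep, "truth")
  expect_equal(truth$lag_s, 2e-6)
  # noiseless recovery of per-trace arrivals to within one sample
  per <- lapply(seq_len(nrow(sweep)), function(i) {
    second_cycle_metrics(sweep$trace[[i]], 60e3)
  })
  arr <- vapply(per, function(m) m$arrival_time, numeric(1))
  offset <- arr - (sweep$true_arrival + 1 / 60e3)
  expect_true(all(abs(offset) <= 1 / 512e3))
  # intact amplitude profile peaks at the flanks, ablated at the centre
  amp_ant <- sweep$true_amplitude[sweep$tympanum == "anterior"]
  expect_equal(sweep$angle_deg[sweep$tympanum == "anterior"][which.max(amp_ant)], 10)
  abl <- gen_angle_sweep(cfg, 60e3, "ablated")
  amp_abl <- abl$true_amplitude[abl$tympanum == "anterior"]
  expect_equal(abl$angle_deg[abl$tympanum == "anterior"][which.max(amp_abl)], 0)
  # quarter-cycle ground truth maps to 90 degrees
  expect_equal(phase_difference_deg(60e3, 0.25 / 60e3), 90)
})

test_that("chirp responses embed a single-degree-of-freedom resonance", {
  cfg <- generator_config(seed = 4, noise_sd = 0)
  ch <- gen_chirp_response(cfg, 100e3, q_factor = 40)
  spec <- chirp_transfer(ch$response, ch$stimulus)
  pk <- resonance_peak(spec, c(80e3, 120e3))
  expect_lt(abs(pk$f_peak - ch$truth$f_peak_analytic), attr(spec, "bin_hz"))
  # flat resonator limit: response == stimulus gives 0 dB
  expect_error(gen_chirp_response(cfg, 10e3), "inside the chirp band")
  # -3 dB width narrows as f0/Q (SDOF closed form, moderate tolerance)
  half_width <- function(q) {
    chq <- gen_chirp_response(cfg, 80e3, q_factor = q)
    sp <- chirp_transfer(chq$response, chq$stimulus)
    gmax <- max(sp$gain_db[sp$frequency > 60e3 & sp$frequency < 100e3])
    sel <- sp$frequency > 60e3 & sp$frequency < 100e3 & sp$gain_db > gmax - 3
    diff(range(sp$frequency[sel]))
  }
  expect_gt(half_width(10), half_width(40))
  expect_equal(half_width(10) / (80e3 / 10), 1, tolerance = 0.35)
})

test_that("threshold matrices honour quantisation, clipping and dropout", {
  cfg0 <- generator_config(seed = 5, missing_prob = 0,
                           threshold_sds_db = rep(0, 21))
  tm0 <- gen_threshold_matrix(cfg0)
  s0 <- summarize_thresholds(tm0)
  quantised <- pmin(pmax(round(cfg0$threshold_means_db / 5) * 5, 40), 90)
  expect_equal(s0$mean_db, quantised)
  expect_true(all(s0$n == 9))
  cfg <- generator_config(seed = 6, missing_prob = 0.15)
  tm <- gen_threshold_matrix(cfg, n_individuals = 60)
  vals <- as.matrix(as.data.frame(tm)[, -1])
  frac <- mean(is.na(vals))
  p <- 0.15; n <- length(vals)
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / n))
  present <- vals[!is.na(vals)]
  expect_true(all(present >= 40 & present <= 90))
  expect_true(all(present %% 5 == 0))
})

test_that("neural traces scale with the on/off amplitude ratio", {
  cfg <- generator_config(seed = 7)
  measure <- function(ratio) {
    nt <- gen_neural_trace(cfg, on_off_ratio = ratio)
    env <- rms_envelope(nt$trace)
    on <- vapply(nt$schedule$on_start, function(s) response_area(env, s + 0.025, 0.475), numeric(1))
    off <- vapply(nt$schedule$off_start, function(s) response_area(env, s + 0.025, 0.475), numeric(1))
    c(on = mean(on), off = mean(off))
  }
  m1 <- measure(1)
  expect_equal(unname(percent_above_background(m1["on"], m1["off"])), 0, tolerance = 2)
  m2 <- measure(2)
  expect_equal(unname(m2["on"] / m1["on"]), 2, tolerance = 0.05)  # area linear in ratio
  m3 <- measure(1.861)
  expect_equal(unname(percent_above_background(m3["on"], m3["off"])), 86.1,
               tolerance = 2)
})
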