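test_that("threshold summaries reproduce every printed mean/SD cell", {
  tm <- table3_matrix()
  s <- summarize_thresholds(tm)
  printed <- table3_printed()
  expect_equal(nrow(s), 21)
  for (i in seq_len(nrow(printed))) {
    row <- s[s$frequency_khz == printed$frequency_khz[i], ]
    dm <- printed_decimals(printed$mean_printed[i])
    ds <- printed_decimals(printed$sd_printed[i])
    expect_equal(round(row$mean_db, dm), as.numeric(printed$mean_printed[i]),
                 info = sprintf("mean at %g kHz", printed$frequency_khz[i]))
    expect_equal(round(row$sd_db, ds), as.numeric(printed$sd_printed[i]),
                 info = sprintf("sd at %g kHz", printed$frequency_khz[i]))
  }
  # brute-force oracle agrees with the dplyr path
  mat <- as.matrix(as.data.frame(tm)[, -1])
  bf <- brute_force_column_summary(mat)
  expect_equal(s$mean_db, unname(bf[, "mean"]))
  expect_equal(s$sd_db, unname(bf[, "sd"]))
  expect_equal(s$n, unname(as.integer(bf[, "n"])))
})

test_that("degenerate threshold columns yield missing summaries", {
  df <- data.frame(id = c("a", "b"), `20` = c(NA, NA), `25` = c(60, NA),
                   `30` = c(55, 65), check.names = FALSE)
  s <- summarize_thresholds(threshold_matrix(df))
  expect_true(is.na(s$mean_db[s$frequency_khz == 20]))
  expect_equal(s$mean_db[s$frequency_khz == 25], 60)
  expect_true(is.na(s$sd_db[s$frequency_khz == 25]))  # sample SD undefined, n = 1
  expect_equal(s$sd_db[s$frequency_khz == 30], sd(c(55, 65)))
})

test_that("band means pool as declared and match brute force on 90-120 kHz", {
  tm <- table3_matrix()
  raw <- band_mean(tm, 90, 120, pooling = "raw")
  mat <- as.matrix(as.data.frame(tm)[, -1])
  freqs <- as.numeric(colnames(mat))
  vals <- as.numeric(mat[, freqs >= 90 & freqs <= 120])
  vals <- vals[!is.na(vals)]
  expect_equal(raw$n, 49)                      # 49 non-missing printed values
  expect_equal(raw$mean_db, mean(vals))
  expect_equal(round(raw$mean_db, 2), 58.06)
  pf <- band_mean(tm, 90, 120, pooling = "per_frequency")
  expect_equal(round(pf$mean_db, 2), 58.07)
  pi_ <- band_mean(tm, 90, 120, pooling = "per_individual")
  expect_equal(round(pi_$mean_db, 2), 58.45)
  # a single-frequency band reduces to the per-frequency summary
  one <- band_mean(tm, 60, 60)
  s <- summarize_thresholds(tm)
  expect_equal(one$mean_db, s$mean_db[s$frequency_khz == 60])
  expect_error(band_mean(tm, 200, 300), "intersect")
})

test_that("threshold matrix CSV round-trips with literal NaN markers", {
  tm <- table3_matrix()
  path <- tempfile(fileext = ".csv")
  write_threshold_matrix(tm, path)
  txt <- readLines(path)
  expect_true(any(grepl("NaN", txt)))
  back <- read_threshold_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(tm))
  # malformed header
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", x = 1), bad, row.names = FALSE)
  expect_error(read_threshold_matrix(bad), "numeric frequencies")
})

test_that("RMS envelope obeys the sinusoid and step-response closed forms", {
  fs <- 15e3
  tau <- 0.66e-3
  tt <- seq(0, 0.2, by = 1 / fs)
  x <- trace(2 * sin(2 * pi * 500 * tt), fs)
  env <- rms_envelope(x, tau)
  settled <- env$samples[seq(1500, length(tt))]
  expect_equal(mean(settled), 2 / sqrt(2), tolerance = 0.02)
  # amplitude step A -> 2A: squared envelope rises by 63% of the step at t = tau
  y <- c(rep(1, 1500), rep(2, 3000))
  stept <- trace(y, fs)
  env2 <- rms_envelope(stept, tau)
  i_tau <- 1500 + round(tau * fs)
  frac <- (env2$samples[i_tau]^2 - 1) / (4 - 1)
  expect_equal(frac, 1 - exp(-1), tolerance = 0.05)
  # scaling commutes
  x2 <- trace(-3 * x$samples, fs)
  expect_equal(rms_envelope(x2, tau)$samples, 3 * env$samples, tolerance = 1e-12)
  # all-zero in, zero out
  expect_true(all(rms_envelope(trace(numeric(100), fs), tau)$samples == 0))
  expect_error(rms_envelope(x, 1e-6), "time_constant")
})

test_that("response areas integrate the envelope and add over windows", {
  fs <- 15e3
  env <- trace(rep(1, fs), fs, unit = "uV")
  expect_equal(response_area(env, 0.1, 0.475), 0.475, tolerance = 1e-6)
  env2 <- trace(rep(2, fs), fs, unit = "uV")
  expect_equal(response_area(env2, 0.1, 0.475), 2 * 0.475, tolerance = 1e-6)
  expect_equal(response_area(trace(numeric(fs), fs), 0.1, 0.475), 0)
  withr::with_seed(8, ramp <- trace(cumsum(runif(fs)), fs))
  a_total <- response_area(ramp, 0.1, 0.4)
  a_split <- response_area(ramp, 0.1, 0.2) + response_area(ramp, 0.3, 0.2)
  expect_equal(a_total, a_split, tolerance = 1e-9)
  expect_error(response_area(env, 0.9, 0.475), "outside")
})

test_that("percent above background matches the printed elevation", {
  expect_equal(percent_above_background(62.7, 62.7 / 1.861), 86.1)
  expect_equal(percent_above_background(5, 5), 0)
  expect_equal(percent_above_background(10, 5), 100)
  expect_error(percent_above_background(1, 0), "positive")
})

test_that("paired on/off test agrees with a hand-computed t statistic", {
  on <- c(10.2, 12.5, 11.8)
  off <- c(8.1, 9.9, 10.0)
  d <- on - off
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  res <- paired_on_off_test(on, off)
  td <- tidy(res)
  expect_equal(td$statistic, t_hand, tolerance = 1e-12)
  expect_equal(td$parameter, 2)
  expect_equal(td$p.value, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  expect_error(paired_on_off_test(c(1, 2, 3), c(1, 2, 3)), "Zero variance")
  expect_error(paired_on_off_test(1, 1), ">= 2")
  # constant positive difference with tiny jitter gives a huge t
  withr::with_seed(9, {
    off2 <- runif(5, 10, 20)
    on2 <- off2 + 3 + rnorm(5, 0, 1e-3)
    expect_gt(glance(paired_on_off_test(on2, off2))$statistic, 1000)
  })
})
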