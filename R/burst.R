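#' Synthesise a sinusoidal tone burst
#'
#' Generates the stimulus used for tympanal time-domain vibrometry: a sine
#' burst of exactly `cycles` periods starting at `onset`, zero elsewhere.
#' The burst length in samples is rounded to the nearest sample; the exact
#' (unrounded) duration `cycles / frequency` is recorded as an attribute.
#'
#' @param frequency Tone frequency, Hz (must be below Nyquist).
#' @param cycles Number of cycles (default 4).
#' @param sample_rate Sampling rate, Hz (default 512 kHz).
#' @param amplitude Peak amplitude (default 1).
#' @param onset Burst onset time, s (default 0).
#' @param duration Total trace duration, s (default onset + burst + one burst
#'   length of silence).
#' @return A [trace()] with attribute `exact_duration` (s).
#' @examples
#' b <- make_tone_burst(60e3, sample_rate = 512e3)
#' length(b)  # burst embedded in a longer trace
#' @export
make_tone_burst <- function(frequency, cycles = 4, sample_rate = 512e3,
                            amplitude = 1, onset = 0, duration = NULL) {
  if (frequency <= 0) abort("`frequency` must be positive.")
  if (frequency >= sample_rate / 2) {
    abort(sprintf("Nyquist violation: %g Hz tone at %g Hz sampling.",
                  frequency, sample_rate))
  }
  burst_dur <- cycles / frequency
  if (is.null(duration)) duration <- onset + 2 * burst_dur
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  y <- numeric(n)
  # the onset is honoured at sub-sample precision: the burst phase is defined
  # relative to the requested onset time, not to the nearest sample
  n_burst <- round(burst_dur * sample_rate)
  idx <- which(t >= onset & t < onset + burst_dur)
  y[idx] <- amplitude * sin(2 * pi * frequency * (t[idx] - onset))
  out <- trace(y, sample_rate)
  attr(out, "exact_duration") <- burst_dur
  attr(out, "burst_samples") <- n_burst
  attr(out, "onset") <- onset
  out
}

#' Band-pass band for a vibrometry test frequency
#'
#' Maps each tone-burst test frequency to the recording band-pass band:
#' 23 kHz -> 10--30 kHz, 40 kHz -> 30--50 kHz, 60 kHz -> 50--70 kHz. Any other
#' frequency falls back to `f` +/- 10 kHz with a warning.
#'
#' @param test_frequency Test frequency, Hz.
#' @return Length-2 numeric vector `c(low, high)` in Hz.
#' @export
bandpass_for <- function(test_frequency) {
  khz <- test_frequency / 1000
  if (isTRUE(all.equal(khz, 23))) return(c(10e3, 30e3))
  if (isTRUE(all.equal(khz, 40))) return(c(30e3, 50e3))
  if (isTRUE(all.equal(khz, 60))) return(c(50e3, 70e3))
  warn(sprintf("No standard band for %g kHz; using +/- 10 kHz.", khz))
  c(max(test_frequency - 10e3, 1), test_frequency + 10e3)
}

#' Zero-phase band-pass filter a trace
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]) so that the filter is zero-phase: arrival times are
#' the downstream measurand and must not be biased by group delay.
#'
#' @param x A [trace()].
#' @param band Length-2 vector `c(low, high)` in Hz, inside (0, Nyquist).
#' @param order Butterworth order per band edge (default 4).
#' @return Filtered [trace()] of the same length.
#' @export
apply_bandpass <- function(x, band, order = 4) {
  stopifnot(inherits(x, "trace"))
  nyq <- x$sample_rate / 2
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq) {
    abort("`band` must satisfy 0 < low < high < Nyquist.")
  }
  bf <- signal::butter(order, band / nyq, type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  trace(y, x$sample_rate, unit = x$unit, t0 = x$t0)
}

# Analytic-signal envelope via FFT Hilbert transform.
signal_envelope <- function(y) {
  n <- length(y)
  Y <- fft(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(Y * h, inverse = TRUE) / n)
}

#' Arrival time and displacement of the second burst oscillation
#'
#' Locates the tone burst in a vibrometry trace and extracts the arrival time
#' of the second oscillation together with the peak displacement within that
#' cycle. The default landmark for "second oscillation" is the second
#' positive-going zero crossing after burst onset; the onset is anchored on
#' the 50% crossing of the analytic (Hilbert) envelope, which sits at a fixed
#' small phase offset from the true onset for a short tone burst, and the
#' crossing is then selected by proximity (one period after the anchor) so
#' that stray noise crossings cannot shift the count. The alternative
#' `"peak"` landmark uses the second cycle's positive peak instead.
#'
#' @param x A [trace()] containing (at most) one burst.
#' @param test_frequency Stimulus frequency, Hz.
#' @param snr_db Minimum envelope peak-to-floor ratio in dB for a detection
#'   (default 15; the envelope of stationary noise alone peaks near 11 dB
#'   above its median, a genuine burst tens of dB above it).
#' @param landmark `"zero_crossing"` (default) or `"peak"`.
#' @return One-row tibble with `arrival_time` (s), `displacement`, `detected`
#'   (logical) and `landmark`. On no detection, times are `NA` and `detected`
#'   is `FALSE`.
#' @export
second_cycle_metrics <- function(x, test_frequency, snr_db = 15,
                                 landmark = c("zero_crossing", "peak")) {
  stopifnot(inherits(x, "trace"))
  landmark <- match.arg(landmark)
  y <- x$samples
  tt <- trace_times(x)
  env <- signal_envelope(y)
  peak <- max(env)
  floor_est <- stats::median(env)
  no_det <- tibble(arrival_time = NA_real_, displacement = NA_real_,
                   detected = FALSE, landmark = landmark)
  if (peak <= 0 || floor_est <= 0) return(no_det)
  if (20 * log10(peak / floor_est) < snr_db) return(no_det)
  period <- 1 / test_frequency
  # onset anchor: the 50% envelope crossing of a short tone burst sits a
  # fixed small fraction (~0.1 period) after the true onset, independent of
  # amplitude, so the second-cycle crossing is selected by proximity rather
  # than by counting (counting is unstable against noise crossings)
  t_on <- tt[which(env >= 0.5 * peak)[1]]
  target <- t_on + 0.9 * period
  z <- which(y[-length(y)] <= 0 & y[-1] > 0)
  if (length(z) < 1) return(no_det)
  cross_t <- vapply(z, function(k) {
    # linear interpolation of the crossing instant
    tt[k] + (0 - y[k]) / (y[k + 1] - y[k]) / x$sample_rate
  }, numeric(1))
  second_cross <- cross_t[which.min(abs(cross_t - target))]
  if (abs(second_cross - target) > period / 2) return(no_det)
  cyc_lo <- second_cross
  cyc_hi <- second_cross + period
  in_cyc <- tt >= cyc_lo & tt < cyc_hi
  if (!any(in_cyc)) return(no_det)
  disp <- max(abs(y[in_cyc]))
  arrival <- if (landmark == "zero_crossing") {
    second_cross
  } else {
    tt[in_cyc][which.max(y[in_cyc])]
  }
  tibble(arrival_time = arrival, displacement = disp,
         detected = TRUE, landmark = landmark)
}

#' Phase difference from an arrival-time difference
#'
#' Converts a difference in arrival times between the anterior and posterior
#' tympana into a phase angle: `phi = 360 * f * |dt|` degrees. The result is
#' not wrapped to \[0, 360) unless requested, so integer numbers of cycles are
#' visible.
#'
#' @param frequency Stimulus frequency, Hz.
#' @param dt Arrival-time difference, s (absolute value is used).
#' @param wrap Wrap to \[0, 360)? Default `FALSE`.
#' @return Phase difference in degrees.
#' @examples
#' phase_difference_deg(60e3, 0.25 / 60e3)  # quarter cycle -> 90 degrees
#' @export
phase_difference_deg <- function(frequency, dt, wrap = FALSE) {
  if (any(frequency <= 0)) abort("`frequency` must be positive.")
  phi <- 360 * frequency * abs(dt)
  if (wrap) phi <- phi %% 360
  phi
}

#' Locate point zero in an angle sweep
#'
#' Point zero is the speaker angle at which the anterior and posterior
#' tympanal responses are phase-matched to the stimulus: the angle minimising
#' the absolute phase difference between the two tympana. Ties are broken
#' towards the angle nearest 0 degrees.
#'
#' @param sweep An angle-sweep tibble with columns `angle_deg`, `tympanum`
#'   (`"anterior"`/`"posterior"`) and list-column `trace` of [trace()] objects,
#'   as produced by [gen_angle_sweep()].
#' @param test_frequency Stimulus frequency, Hz.
#' @param ... Passed to [second_cycle_metrics()].
#' @return One-row tibble with `point_zero_deg`, `n_valid_angles`, and the
#'   per-angle phase table in list-column `angles`.
#' @export
find_point_zero <- function(sweep, test_frequency, ...) {
  stopifnot(is.data.frame(sweep),
            all(c("angle_deg", "tympanum", "trace") %in% names(sweep)))
  per <- sweep |>
    dplyr::mutate(metrics = purrr::map(.data$trace, second_cycle_metrics,
                                       test_frequency = test_frequency, ...)) |>
    tidyr::unnest("metrics") |>
    dplyr::select("angle_deg", "tympanum", "arrival_time", "detected")
  wide <- per |>
    tidyr::pivot_wider(names_from = "tympanum", values_from = c("arrival_time", "detected"))
  ok <- wide$detected_anterior & wide$detected_posterior
  wide <- wide[which(ok), , drop = FALSE]
  if (nrow(wide) < 3) {
    abort("Point zero needs detections on both tympana at >= 3 angles.")
  }
  wide$dphi <- phase_difference_deg(
    test_frequency, wide$arrival_time_anterior - wide$arrival_time_posterior)
  best <- min(wide$dphi)
  cand <- wide$angle_deg[wide$dphi <= best + 1e-9]
  pz <- cand[which.min(abs(cand))]
  tibble(point_zero_deg = pz, n_valid_angles = nrow(wide),
         angles = list(as_tibble(wide)))
}

#' Transfer spectrum of a chirp response against a reference
#'
#' Divides the response spectrum by the stimulus (reference) spectrum to give
#' frequency-specific gain, emulating reference-spectrum subtraction in dB.
#' Spectra are mean Welch periodograms over Hamming-windowed segments.
#'
#' @param response A [trace()].
#' @param stimulus A [trace()] at the same sampling rate, or `NULL` for a flat
#'   (unit) reference.
#' @param nfft Segment/FFT length (default 1024).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return A `gain_spectrum` tibble with columns `frequency` (Hz) and
#'   `gain_db`; bin spacing is recorded in attribute `bin_hz`.
#' @export
chirp_transfer <- function(response, stimulus = NULL, nfft = 1024,
                           overlap = 0.5) {
  stopifnot(inherits(response, "trace"))
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "trace"))
    if (!isTRUE(all.equal(stimulus$sample_rate, response$sample_rate))) {
      abort("Response and stimulus sampling rates differ.")
    }
    if (length(stimulus) != length(response)) {
      abort("Response and stimulus lengths differ; no padding policy is applied.")
    }
  }
  p_resp <- welch_psd(response$samples, response$sample_rate, nfft, overlap)
  if (is.null(stimulus)) {
    ref <- rep(1, nrow(p_resp))
  } else {
    ref <- welch_psd(stimulus$samples, stimulus$sample_rate, nfft, overlap)$power
  }
  if (any(ref <= 0)) abort("Reference spectrum has zero-power bins.")
  out <- tibble(frequency = p_resp$frequency,
                gain_db = 10 * log10(p_resp$power / ref))
  attr(out, "bin_hz") <- response$sample_rate / nfft
  attr(out, "nfft") <- nfft
  attr(out, "overlap") <- overlap
  class(out) <- c("gain_spectrum", class(out))
  out
}

# Mean Welch periodogram (Hamming window); power per bin, one-sided.
welch_psd <- function(y, fs, nfft = 1024, overlap = 0.5) {
  n <- length(y)
  if (n < nfft) abort(sprintf("Trace (%d samples) shorter than nfft = %d.", n, nfft))
  w <- signal::hamming(nfft)
  hop <- max(1L, round(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- y[s:(s + nfft - 1L)] * w
    S <- Mod(fft(seg))^2
    acc <- acc + S[seq_len(nfft %/% 2 + 1)]
  }
  acc <- acc / length(starts) / sum(w^2)
  tibble(frequency = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft, power = acc)
}

#' @method autoplot gain_spectrum
#' @export
autoplot.gain_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency / 1000,
                                       y = .data$gain_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (kHz)", y = "gain (dB)")
}

#' Interpolated resonance peak of a gain spectrum
#'
#' Finds the maximum of the spectrum within a frequency range and refines the
#' discrete maximum by quadratic interpolation through the three surrounding
#' bins, so the estimate does not depend on the sweep step. A maximum on the
#' range boundary is flagged (`boundary = TRUE`) and not interpolated; a flat
#' spectrum yields a no-peak result. Exact ties resolve to the lowest
#' frequency and are flagged.
#'
#' @param spectrum A `gain_spectrum` (or any tibble with `frequency` and a
#'   gain column).
#' @param f_range Length-2 range in Hz (default: full support).
#' @param value_col Name of the gain column (default `"gain_db"`).
#' @return One-row tibble: `f_peak`, `gain_peak`, `boundary`, `tie`, `found`.
#' @export
resonance_peak <- function(spectrum, f_range = NULL, value_col = "gain_db") {
  stopifnot(is.data.frame(spectrum), "frequency" %in% names(spectrum),
            value_col %in% names(spectrum))
  f <- spectrum$frequency
  g <- spectrum[[value_col]]
  if (is.null(f_range)) f_range <- range(f)
  keep <- which(f >= f_range[1] & f <= f_range[2])
  if (length(keep) == 0) abort("`f_range` does not intersect the spectrum.")
  f <- f[keep]; g <- g[keep]
  if (diff(range(g)) < 1e-12) {
    return(tibble(f_peak = NA_real_, gain_peak = NA_real_, boundary = FALSE,
                  tie = FALSE, found = FALSE))
  }
  gmax <- max(g)
  imaxs <- which(abs(g - gmax) < 1e-12)
  tie <- length(imaxs) > 1
  i <- imaxs[1]
  if (i == 1 || i == length(g)) {
    return(tibble(f_peak = f[i], gain_peak = g[i], boundary = TRUE,
                  tie = tie, found = TRUE))
  }
  # quadratic through (f[i-1], g[i-1]), (f[i], g[i]), (f[i+1], g[i+1])
  d1 <- g[i] - g[i - 1]; d2 <- g[i] - g[i + 1]
  denom <- d1 + d2
  delta <- if (denom > 0) 0.5 * (d1 - d2) / denom else 0
  h <- (f[i + 1] - f[i - 1]) / 2
  f_peak <- f[i] + delta * h
  gain_peak <- g[i] + 0.25 * (d1 - d2) * delta
  tibble(f_peak = f_peak, gain_peak = gain_peak, boundary = FALSE,
         tie = tie, found = TRUE)
}

#' Scale a frequency by a 3D-print scale factor
#'
#' Stimuli delivered to enlarged 3D-printed ear models are scaled down by the
#' print scale so wavelengths match the life-size geometry: a 1:11.43 print of
#' an ear tested with a 60 kHz equivalent tone receives 60/11.43 = 5.25 kHz.
#'
#' @param frequency Frequency in Hz (or kHz; units pass through).
#' @param print_scale Positive scale factor (e.g. 11.43).
#' @return `frequency / print_scale`.
#' @export
scale_frequency <- function(frequency, print_scale) {
  if (any(print_scale <= 0)) abort("`print_scale` must be positive.")
  frequency / print_scale
}
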