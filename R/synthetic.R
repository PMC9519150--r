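#' Configuration for the synthetic-data generators
#'
#' Collects the seeds, noise levels and literature-derived defaults shared by
#' all generators. Defaults emulate the study system: slit areas
#' 0.16 +/- 0.01 mm^2 and cavity volumes 0.14/0.15 +/- 0.01 mm^3, tympanal
#' resonances at 107.84 (posterior) and 111.13 (anterior) kHz, the behavioural
#' threshold grid 20-120 kHz in 5 kHz steps with its printed per-frequency
#' means and standard deviations, a ~2 us anterior-to-posterior arrival lag at
#' the extreme speaker angle, and the three sympatric gleaning-bat call
#' templates.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param noise_sd Additive Gaussian noise for signal generators, in the
#'   signal's unit (default 0.02).
#' @param morphometry_means,morphometry_sds Named lists with `slit_area_mm2`
#'   and `cavity_volume_mm3`.
#' @param tympanum_resonances_khz Named vector, anterior/posterior tympanal
#'   resonance peaks in kHz.
#' @param threshold_means_db,threshold_sds_db Per-frequency behavioural
#'   threshold means/SDs (dB SPL) on `threshold_grid_khz`.
#' @param threshold_grid_khz Stimulus frequency grid in kHz.
#' @param missing_prob Probability a behavioural threshold is missing
#'   (no response), default 0.1.
#' @param posterior_lag_s Arrival lag of the posterior tympanum at the extreme
#'   (+10 degree) speaker angle, seconds (default 2e-6).
#' @param speaker_arc_radius_m Speaker arc radius (default 0.12 m; 1 degree
#'   steps are 0.56 mm of arc).
#' @param bat_templates Template tibble as [bat_call_templates()].
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(
    seed = 1L,
    noise_sd = 0.02,
    morphometry_means = list(slit_area_mm2 = 0.16, cavity_volume_mm3 = 0.14),
    morphometry_sds = list(slit_area_mm2 = 0.01, cavity_volume_mm3 = 0.01),
    tympanum_resonances_khz = c(posterior = 107.84, anterior = 111.13),
    threshold_grid_khz = seq(20, 120, by = 5),
    threshold_means_db = c(80, 63, 57.5, 53, 57.5, 58, 55, 59, 58.8, 60, 62.1,
                           59, 57, 58.6, 57.1, 58.3, 60, 56, 59, 58, 58),
    threshold_sds_db = c(9, 7, 4.63, 4, 7.07, 6.6, 5.77, 7.5, 3.54, 5.77, 10.4,
                         9.7, 5.7, 7.48, 4.88, 6.06, 8.7, 5.3, 7.9, 7, 6.4),
    missing_prob = 0.1,
    posterior_lag_s = 2e-6,
    speaker_arc_radius_m = 0.12,
    bat_templates = bat_call_templates()) {
  stopifnot(missing_prob >= 0, missing_prob <= 1, noise_sd >= 0,
            length(threshold_means_db) == length(threshold_grid_khz),
            length(threshold_sds_db) == length(threshold_grid_khz),
            all(threshold_sds_db >= 0))
  structure(as.list(environment()), class = "generator_config")
}

# Run code with a deterministic RNG stream derived from (seed, tag) without
# disturbing the caller's RNG state.
with_gen_seed <- function(config, tag, code) {
  sub_seed <- (config$seed * 7919L + sum(utf8ToInt(tag)) * 131L) %% .Machine$integer.max
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed)
  force(code)
}

# Truncated-normal draws on (0, Inf) by rejection.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

#' Generate synthetic cavity morphometry
#'
#' Truncated-normal (positive support) draws of slit area and cavity volume
#' around the configured means/SDs, one row per ear.
#'
#' @param config A [generator_config()].
#' @param n_ears Number of ears (>= 1).
#' @return A morphometry tibble as [cavity_morphometry()], with a `truth`
#'   attribute holding the configured means.
#' @export
gen_morphometry <- function(config, n_ears) {
  stopifnot(inherits(config, "generator_config"), n_ears >= 1)
  with_gen_seed(config, "morphometry", {
    m <- config$morphometry_means; s <- config$morphometry_sds
    out <- cavity_morphometry(
      slit_area_mm2 = rtruncnorm_pos(n_ears, m$slit_area_mm2, s$slit_area_mm2),
      cavity_volume_mm3 = rtruncnorm_pos(n_ears, m$cavity_volume_mm3,
                                         s$cavity_volume_mm3),
      label = sprintf("ear%02d", seq_len(n_ears))
    )
    attr(out, "truth") <- list(means = m, sds = s)
    out
  })
}

#' Generate a synthetic tone-burst angle sweep
#'
#' Emulates simultaneous two-laser vibrometry of both tympana while a speaker
#' sweeps -10..10 degrees in 1 degree steps: 4-cycle bursts whose arrival
#' times follow an angle-dependent path difference that vanishes at the
#' symmetry axis (`axis_deg`, the injected point zero) and reaches the
#' configured posterior lag at +10 degrees. With pinnae intact, displacement
#' amplitudes peak at +/-10 degrees (each cavity faces its own side) with the
#' minimum near point zero; ablated, amplitudes peak at point zero.
#'
#' @param config A [generator_config()].
#' @param test_frequency Stimulus frequency, Hz (23, 40 or 60 kHz in the
#'   emulated protocol).
#' @param pinnae_state `"intact"` or `"ablated"`.
#' @param axis_deg Injected symmetry axis (ground-truth point zero), default 0.
#' @param sample_rate Sampling rate, Hz (default 512 kHz).
#' @return A tibble with columns `angle_deg`, `tympanum`, `pinnae_state`,
#'   `trace` (list of [trace()]), and ground-truth columns `true_arrival` (s)
#'   and `true_amplitude` (nm). Attribute `truth` records the axis and lag.
#' @export
gen_angle_sweep <- function(config, test_frequency,
                            pinnae_state = c("intact", "ablated"),
                            axis_deg = 0, sample_rate = 512e3) {
  stopifnot(inherits(config, "generator_config"))
  pinnae_state <- match.arg(pinnae_state)
  angles <- -10:10
  t0 <- 1e-3
  lag <- config$posterior_lag_s
  with_gen_seed(config, paste0("sweep", test_frequency, pinnae_state, axis_deg), {
    rows <- purrr::map(angles, function(a) {
      rel <- a - axis_deg
      # antisymmetric path difference, split between the two tympana; the
      # posterior lag is reached at the extreme angle
      dpath <- lag * sin(rel * pi / 180) / sin(10 * pi / 180)
      arr_ant <- t0 - dpath / 2
      arr_post <- t0 + dpath / 2
      if (pinnae_state == "intact") {
        amp_ant <- 1.1 + 2.0 * exp(-((rel - 10) / 8)^2)
        amp_post <- 1.1 + 2.0 * exp(-((rel + 10) / 8)^2)
      } else {
        amp_ant <- 1.0 + 2.0 * exp(-(rel / 12)^2)
        amp_post <- 1.0 + 2.0 * exp(-(rel / 12)^2)
      }
      make_pair <- function(onset, amp) {
        b <- make_tone_burst(test_frequency, cycles = 4,
                             sample_rate = sample_rate, amplitude = amp,
                             onset = onset, duration = 2 * t0)
        y <- b$samples + rnorm(length(b$samples), 0, config$noise_sd)
        trace(y, sample_rate, unit = "nm")
      }
      tibble(
        angle_deg = a,
        tympanum = c("anterior", "posterior"),
        pinnae_state = pinnae_state,
        trace = list(make_pair(arr_ant, amp_ant), make_pair(arr_post, amp_post)),
        true_arrival = c(arr_ant, arr_post),
        true_amplitude = c(amp_ant, amp_post)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(axis_deg = axis_deg, lag_s = lag, onset_s = t0,
                               test_frequency = test_frequency)
    out
  })
}

#' Generate a synthetic chirp stimulus/response pair
#'
#' Passes a periodic linear chirp (20-120 kHz by default) through a
#' single-degree-of-freedom resonator with natural frequency `resonance_f0`
#' and quality factor `q_factor`, adding Gaussian noise, to emulate tympanal
#' responses to broadband stimulation.
#'
#' @param config A [generator_config()].
#' @param resonance_f0 Resonator natural frequency, Hz (must lie inside the
#'   chirp band).
#' @param q_factor Quality factor (default 30).
#' @param band Chirp band, Hz (default c(20e3, 120e3)).
#' @param duration Chirp duration, s (default 0.05).
#' @param sample_rate Sampling rate, Hz (default 512 kHz).
#' @return List with `stimulus` and `response` [trace()]s and `truth`
#'   (f0, q, analytic peak frequency of the transfer magnitude).
#' @export
gen_chirp_response <- function(config, resonance_f0, q_factor = 30,
                               band = c(20e3, 120e3), duration = 0.05,
                               sample_rate = 512e3) {
  stopifnot(inherits(config, "generator_config"))
  if (resonance_f0 <= band[1] || resonance_f0 >= band[2]) {
    abort("`resonance_f0` must lie inside the chirp band.")
  }
  with_gen_seed(config, paste0("chirp", resonance_f0, q_factor), {
    n <- round(duration * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    k <- diff(band) / duration
    stim <- sin(2 * pi * (band[1] * t + k * t^2 / 2))
    # SDOF transfer applied in the frequency domain
    fgrid <- c(seq(0, n %/% 2), seq(-((n - 1) %/% 2), -1)) * sample_rate / n
    w <- 2 * pi * fgrid
    w0 <- 2 * pi * resonance_f0
    H <- w0^2 / (w0^2 - w^2 + 1i * w * w0 / q_factor)
    resp <- Re(fft(fft(stim) * H, inverse = TRUE) / n)
    stim <- stim + rnorm(n, 0, config$noise_sd)
    resp <- resp + rnorm(n, 0, config$noise_sd)
    f_peak <- resonance_f0 * sqrt(1 - 1 / (2 * q_factor^2))
    list(stimulus = trace(stim, sample_rate, unit = "Pa"),
         response = trace(resp, sample_rate, unit = "m/s"),
         truth = list(f0 = resonance_f0, q = q_factor,
                      f_peak_analytic = f_peak))
  })
}

#' Generate a synthetic behavioural threshold matrix
#'
#' Normal draws around the configured per-frequency means/SDs, rounded to the
#' 5 dB staircase grid, clipped to the tested range \[40, 90\] dB SPL, with
#' entries deleted (no response) with probability `missing_prob`.
#'
#' @param config A [generator_config()].
#' @param n_individuals Number of individuals (default 9).
#' @return A [threshold_matrix()] with attribute `truth` (configured means
#'   and SDs).
#' @export
gen_threshold_matrix <- function(config, n_individuals = 9) {
  stopifnot(inherits(config, "generator_config"), n_individuals >= 1)
  with_gen_seed(config, "thresholds", {
    grid <- config$threshold_grid_khz
    mat <- sapply(seq_along(grid), function(j) {
      v <- rnorm(n_individuals, config$threshold_means_db[j],
                 config$threshold_sds_db[j])
      v <- pmin(pmax(round(v / 5) * 5, 40), 90)
      v[runif(n_individuals) < config$missing_prob] <- NA_real_
      v
    })
    mat <- matrix(mat, nrow = n_individuals)
    df <- data.frame(id = sprintf("S%02d", seq_len(n_individuals)),
                     check.names = FALSE)
    for (j in seq_along(grid)) df[[as.character(grid[j])]] <- mat[, j]
    out <- threshold_matrix(df)
    attr(out, "truth") <- list(means = config$threshold_means_db,
                               sds = config$threshold_sds_db,
                               missing_prob = config$missing_prob)
    out
  })
}

#' Generate a synthetic auditory-nerve trace
#'
#' Gaussian background activity whose amplitude is multiplied by
#' `on_off_ratio` during stimulus-ON windows, sampled at the neural recording
#' rate (15 kHz) on a 0.5 s ON / 0.5 s OFF schedule.
#'
#' @param config A [generator_config()].
#' @param n_pulses Number of ON/OFF pulse pairs (default 10).
#' @param on_off_ratio Amplitude ratio ON/OFF (>= 1).
#' @param background_sd Background amplitude in microvolts (default 20).
#' @param pulse_s ON (and OFF) window length, s (default 0.5).
#' @param sample_rate Sampling rate, Hz (default 15 kHz).
#' @return List with `trace` (unit uV) and `schedule` tibble
#'   (`pulse`, `on_start`, `off_start`, each in seconds).
#' @export
gen_neural_trace <- function(config, n_pulses = 10, on_off_ratio = 1.861,
                             background_sd = 20, pulse_s = 0.5,
                             sample_rate = 15e3) {
  stopifnot(inherits(config, "generator_config"), on_off_ratio >= 1)
  with_gen_seed(config, paste0("neural", on_off_ratio), {
    n_per <- round(pulse_s * sample_rate)
    # a short tail of background keeps the last OFF window inside the trace
    n <- 2L * n_pulses * n_per + max(4L, round(0.01 * sample_rate))
    y <- rnorm(n, 0, background_sd)
    on_starts <- (seq_len(n_pulses) - 1) * 2 * pulse_s
    for (p in seq_len(n_pulses)) {
      i0 <- (p - 1L) * 2L * n_per + 1L
      y[i0:(i0 + n_per - 1L)] <- y[i0:(i0 + n_per - 1L)] * on_off_ratio
    }
    list(
      trace = trace(y, sample_rate, unit = "uV"),
      schedule = tibble(pulse = seq_len(n_pulses), on_start = on_starts,
                        off_start = on_starts + pulse_s),
      truth = list(on_off_ratio = on_off_ratio, background_sd = background_sd)
    )
  })
}

#' Synthesise a bat echolocation call from template parameters
#'
#' Builds a downward frequency-modulated sweep whose composite power spectrum
#' has the template's peak frequency and -20 dB minimum/maximum bounds by
#' construction: the spectrum magnitude is shaped as a two-sided parabola in
#' dB anchored at the bounds, the spectral phase encodes a linear downward
#' group delay spanning the call duration, and a weak (-26 dB) second-harmonic
#' ridge is added below Nyquist for the multi-harmonic character.
#'
#' @param template One row of [bat_call_templates()] (or compatible tibble
#'   with `peak_khz`, `fmin_khz`, `fmax_khz`, `duration_ms`).
#' @param sample_rate Sampling rate, Hz (default 512 kHz); `fmax` must be
#'   below Nyquist.
#' @param config Optional [generator_config()] for additive noise (default
#'   noiseless).
#' @return A [trace()] with attribute `truth` (the template row).
#' @export
gen_bat_call <- function(template, sample_rate = 512e3, config = NULL) {
  stopifnot(is.data.frame(template), nrow(template) == 1)
  fp <- template$peak_khz * 1000
  f1 <- template$fmin_khz * 1000
  f2 <- template$fmax_khz * 1000
  dur <- template$duration_ms / 1000
  if (f2 >= sample_rate / 2) {
    abort("Template fmax is at or above Nyquist; raise `sample_rate`.")
  }
  stopifnot(f1 < fp, fp < f2)
  n <- 2048L
  f <- (seq_len(n %/% 2 + 1) - 1) * sample_rate / n
  # two-sided parabolic dB envelope: exactly -20 dB at f1 and f2
  a_db <- ifelse(f <= fp,
                 -20 * ((fp - f) / (fp - f1))^2,
                 -20 * ((f - fp) / (f2 - fp))^2)
  a_db[a_db < -60] <- -Inf
  amp <- 10^(a_db / 20)
  # group delay: downward sweep across the -60 dB support over the duration
  supp <- which(is.finite(a_db))
  f_lo <- f[supp[1]]; f_hi <- f[supp[length(supp)]]
  tau0 <- 2e-4
  tau <- tau0 + (f_hi - pmin(pmax(f, f_lo), f_hi)) / (f_hi - f_lo) * dur
  dphi <- -2 * pi * tau * (sample_rate / n)   # phase increment per bin
  phase <- cumsum(dphi)
  X <- amp * exp(1i * phase)
  # weak second harmonic ridge
  h_ok <- which(2 * f < 0.95 * sample_rate / 2 & is.finite(a_db))
  X2 <- complex(length.out = length(f))
  for (i in h_ok) {
    j <- round(2 * f[i] / (sample_rate / n)) + 1L
    if (j <= length(f)) X2[j] <- X2[j] + amp[i] * 10^(-26 / 20) * exp(1i * 2 * phase[i])
  }
  X <- X + X2
  full <- c(X, Conj(rev(X[2:(n %/% 2)])))
  y <- Re(fft(full, inverse = TRUE) / n)
  if (!is.null(config) && config$noise_sd > 0) {
    y <- with_gen_seed(config, "batcall",
                       y + rnorm(length(y), 0, config$noise_sd * stats::sd(y)))
  }
  out <- trace(y, sample_rate, unit = "Pa")
  attr(out, "truth") <- template
  out
}
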