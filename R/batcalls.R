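#' Spectrogram with standard bioacoustics settings
#'
#' Short-time Fourier magnitude with the conventional call-analysis settings:
#' FFT size 512, Hamming window, 50 % overlap.
#'
#' @param x A [trace()] at least `fft_size` samples long.
#' @param fft_size FFT/window length (default 512).
#' @param overlap Overlap fraction (default 0.5).
#' @return A list of class `"spectrogram"`: `magnitude` (freq x time),
#'   `frequency` (Hz), `time` (s, window centres), `bin_hz`, `hop_s`.
#' @export
spectrogram <- function(x, fft_size = 512, overlap = 0.5) {
  stopifnot(inherits(x, "trace"))
  y <- x$samples
  if (length(y) < fft_size) {
    abort(sprintf("Trace (%d samples) shorter than fft_size = %d.",
                  length(y), fft_size))
  }
  w <- signal::hamming(fft_size)
  hop <- max(1L, round(fft_size * (1 - overlap)))
  starts <- seq(1L, length(y) - fft_size + 1L, by = hop)
  nf <- fft_size %/% 2 + 1
  mag <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- y[starts[j]:(starts[j] + fft_size - 1L)] * w
    mag[, j] <- Mod(fft(seg))[seq_len(nf)]
  }
  structure(list(
    magnitude = mag,
    frequency = (seq_len(nf) - 1) * x$sample_rate / fft_size,
    time = x$t0 + (starts - 1 + fft_size / 2) / x$sample_rate,
    bin_hz = x$sample_rate / fft_size,
    hop_s = hop / x$sample_rate
  ), class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d freq bins x %d frames, %g Hz resolution>\n",
              nrow(x$magnitude), ncol(x$magnitude), x$bin_hz))
  invisible(x)
}

#' Tidy a spectrogram to a long tibble
#' @param x A [spectrogram()].
#' @param ... Unused.
#' @return Tibble with `time`, `frequency`, `magnitude`.
#' @method tidy spectrogram
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble(
    time = rep(x$time, each = length(x$frequency)),
    frequency = rep(x$frequency, times = length(x$time)),
    magnitude = as.numeric(x$magnitude)
  )
}

#' @method autoplot spectrogram
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidy(object)
  df$db <- 20 * log10(pmax(df$magnitude, max(df$magnitude) * 1e-6))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency / 1000,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (kHz)")
}

#' Power spectrum of a full trace
#'
#' Single periodogram of the whole trace (optionally zero-padded), the
#' composite spectrum on which echolocation call parameters are measured.
#'
#' @param x A [trace()].
#' @param nfft FFT length (default: next power of two >= trace length, minimum
#'   512).
#' @return Tibble with `frequency` (Hz) and `power`.
#' @export
power_spectrum <- function(x, nfft = NULL) {
  stopifnot(inherits(x, "trace"))
  n <- length(x$samples)
  if (is.null(nfft)) nfft <- max(512L, 2^ceiling(log2(n)))
  y <- c(x$samples, numeric(nfft - n))
  P <- Mod(fft(y))^2
  nf <- nfft %/% 2 + 1
  tibble(frequency = (seq_len(nf) - 1) * x$sample_rate / nfft,
         power = P[seq_len(nf)])
}

#' Echolocation call parameters from a power spectrum
#'
#' Peak frequency is the bin with maximum power; minimum and maximum call
#' frequencies are the outermost frequencies at which the spectrum crosses
#' `threshold_db` below the peak level (lowest crossing below the peak,
#' highest above it), linearly interpolated in dB between bins. A spectrum
#' that never falls below the threshold on one side is flagged at the support
#' edge.
#'
#' @param spec A tibble with `frequency` (Hz) and `power` columns (power, not
#'   dB), e.g. from [power_spectrum()].
#' @param threshold_db Threshold relative to peak, dB (default -20).
#' @param duration_s Optional known call duration (s), passed through.
#' @param species Optional label, passed through.
#' @return One-row tibble of class `"bat_call_params"`: `species`,
#'   `duration_ms`, `peak_khz`, `fmin_khz`, `fmax_khz`, `fmin_at_edge`,
#'   `fmax_at_edge`.
#' @export
call_params <- function(spec, threshold_db = -20, duration_s = NA_real_,
                        species = NA_character_) {
  stopifnot(is.data.frame(spec), all(c("frequency", "power") %in% names(spec)))
  f <- spec$frequency
  p <- spec$power
  if (diff(range(p)) <= 0) abort("Spectrum is flat; no call parameters.")
  db <- 10 * log10(pmax(p, max(p) * 1e-12)) - 10 * log10(max(p))
  ipk <- which.max(db)
  thr <- threshold_db
  # lowest frequency below the peak where the spectrum is at/below threshold
  below <- which(db[seq_len(ipk)] <= thr)
  if (length(below)) {
    # outermost crossing = first rise above thr scanning up from the low edge
    j <- min(which(db[seq_len(ipk)] > thr))
    fmin <- if (j > 1) {
      f[j - 1] + (thr - db[j - 1]) * (f[j] - f[j - 1]) / (db[j] - db[j - 1])
    } else f[1]
    fmin_edge <- FALSE
  } else {
    fmin <- f[1]; fmin_edge <- TRUE
  }
  above <- which(db[ipk:length(db)] <= thr)
  if (length(above)) {
    # outermost crossing = last super-threshold bin scanning down from the top
    jj <- max(which(db[ipk:length(db)] > thr)) + ipk - 1L
    if (jj < length(db)) {
      fmax <- f[jj] + (thr - db[jj]) * (f[jj + 1] - f[jj]) / (db[jj + 1] - db[jj])
    } else {
      fmax <- f[length(f)]
    }
    fmax_edge <- FALSE
  } else {
    fmax <- f[length(f)]; fmax_edge <- TRUE
  }
  out <- tibble(
    species = species,
    duration_ms = duration_s * 1000,
    peak_khz = f[ipk] / 1000,
    fmin_khz = fmin / 1000,
    fmax_khz = fmax / 1000,
    fmin_at_edge = fmin_edge,
    fmax_at_edge = fmax_edge
  )
  class(out) <- c("bat_call_params", class(out))
  out
}

#' Fraction of a bat call band covered by a gain band
#'
#' Interval overlap `|gain ∩ call| / |call|`, used to quantify how much of a
#' bat's echolocation bandwidth falls inside the pinnal cavity gain band.
#'
#' @param gain_band Length-2 numeric `(f1, f2)`.
#' @param call_band Length-2 numeric `(f3, f4)`; must be non-degenerate.
#' @return Overlap fraction in \[0, 1\].
#' @examples
#' band_overlap(c(60, 120), c(34.9, 99.2))  # ~0.61
#' @export
band_overlap <- function(gain_band, call_band) {
  gain_band <- sort(as.numeric(gain_band))
  call_band <- sort(as.numeric(call_band))
  if (length(gain_band) != 2 || length(call_band) != 2 ||
      diff(call_band) <= 0 || diff(gain_band) < 0) {
    abort("Bands must be length-2 intervals; the call band must be non-degenerate.")
  }
  inter <- max(0, min(gain_band[2], call_band[2]) - max(gain_band[1], call_band[1]))
  inter / diff(call_band)
}

#' Printed echolocation call parameters of three sympatric gleaning bats
#'
#' Reference call parameters (means) for the three co-occurring insectivorous
#' gleaning bat species used as templates by [gen_bat_call()]: call duration,
#' peak frequency, and -20 dB minimum/maximum frequencies.
#'
#' @return A tibble with columns `species`, `duration_ms`, `peak_khz`,
#'   `fmin_khz`, `fmax_khz`.
#' @export
bat_call_templates <- function() {
  tibble(
    species = c("Gardnerycteris crenulatum", "Tonatia saurophila",
                "Micronycteris microtis"),
    duration_ms = c(0.69, 0.69, 0.57),
    peak_khz = c(71.1, 71.1, 97.6),
    fmin_khz = c(63.2, 34.9, 60.3),
    fmax_khz = c(95.9, 99.2, 136.4)
  )
}
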