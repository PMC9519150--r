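#' Behavioural threshold matrix
#'
#' Validating constructor for behavioural audiogram data: individuals by
#' frequencies, thresholds in dB SPL, `NA`/`NaN` for stimuli that evoked no
#' response.
#'
#' @param data A data frame whose first column is the individual identifier and
#'   whose remaining column names are stimulus frequencies in kHz.
#' @return A tibble of class `"threshold_matrix"` in long-friendly wide form.
#' @export
threshold_matrix <- function(data) {
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  freqs <- suppressWarnings(as.numeric(names(data)[-1]))
  if (anyNA(freqs)) {
    abort(paste0(
      "Threshold matrix columns after the first must be numeric frequencies ",
      "(kHz). Expected schema: id, 20, 25, ..., 120."
    ))
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    abort("Frequency columns must be strictly increasing.")
  }
  out <- as_tibble(data)
  names(out)[1] <- "id"
  class(out) <- c("threshold_matrix", class(out))
  out
}

#' Read/write a behavioural threshold matrix CSV
#'
#' The on-disk layout mirrors a printed audiogram table: rows are individuals,
#' columns are stimulus frequencies in kHz, and the literal string `NaN` marks
#' stimuli with no behavioural response. Round-trips losslessly.
#'
#' @param path CSV path.
#' @param x A `threshold_matrix`.
#' @return `read_threshold_matrix` returns a `threshold_matrix`;
#'   `write_threshold_matrix` returns `path` invisibly.
#' @export
read_threshold_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = c("NaN", "NA"))
  threshold_matrix(df)
}

#' @rdname read_threshold_matrix
#' @export
write_threshold_matrix <- function(x, path) {
  stopifnot(inherits(x, "threshold_matrix"))
  df <- as.data.frame(x)
  for (j in seq(2, ncol(df))) df[[j]] <- ifelse(is.na(df[[j]]), "NaN", df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frequency summary of a threshold matrix
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) per
#' stimulus frequency, ignoring missing (no-response) entries. A frequency with
#' no responses yields `NA` summaries; a single response yields its value with
#' `NA` standard deviation (sample SD is undefined for n = 1).
#'
#' @param x A [threshold_matrix()].
#' @return A tibble with columns `frequency_khz`, `mean_db`, `sd_db`, `n`.
#' @export
summarize_thresholds <- function(x) {
  stopifnot(inherits(x, "threshold_matrix"))
  long <- tidyr::pivot_longer(as_tibble(x), -"id",
                              names_to = "frequency_khz", values_to = "db") |>
    dplyr::mutate(frequency_khz = as.numeric(.data$frequency_khz))
  long |>
    dplyr::group_by(.data$frequency_khz) |>
    dplyr::summarise(
      mean_db = if (any(!is.na(.data$db))) mean(.data$db, na.rm = TRUE) else NA_real_,
      sd_db = if (sum(!is.na(.data$db)) > 1) sd(.data$db, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data$db)),
      .groups = "drop"
    )
}

#' Pooled threshold over a frequency band
#'
#' Summarises thresholds across a band of frequencies under an explicit
#' pooling mode: `"raw"` pools every non-missing entry in the band,
#' `"per_frequency"` averages the per-frequency means, and `"per_individual"`
#' averages each individual's band mean before pooling across individuals.
#' The pooling mode is recorded in the output because the three modes differ
#' on ragged (missing-value) matrices.
#'
#' @param x A [threshold_matrix()].
#' @param f_low,f_high Band limits in kHz (inclusive).
#' @param pooling `"raw"` (default), `"per_frequency"` or `"per_individual"`.
#' @return One-row tibble: `mean_db`, `sd_db`, `n`, `pooling`, `f_low`,
#'   `f_high`.
#' @export
band_mean <- function(x, f_low, f_high,
                      pooling = c("raw", "per_frequency", "per_individual")) {
  stopifnot(inherits(x, "threshold_matrix"))
  pooling <- match.arg(pooling)
  freqs <- as.numeric(names(x)[-1])
  keep <- freqs >= f_low & freqs <= f_high
  if (!any(keep)) abort("Band does not intersect the frequency grid.")
  sub <- as.matrix(x[, c(FALSE, keep), drop = FALSE])
  vals <- as.numeric(sub)
  if (all(is.na(vals))) abort("Band contains no non-missing thresholds.")
  if (pooling == "raw") {
    v <- vals[!is.na(vals)]
  } else if (pooling == "per_frequency") {
    v <- apply(sub, 2, mean, na.rm = TRUE)
    v <- v[is.finite(v)]
  } else {
    v <- apply(sub, 1, mean, na.rm = TRUE)
    v <- v[is.finite(v)]
  }
  tibble(mean_db = mean(v),
         sd_db = if (length(v) > 1) sd(v) else NA_real_,
         n = length(v), pooling = pooling, f_low = f_low, f_high = f_high)
}

#' @method autoplot threshold_matrix
#' @export
autoplot.threshold_matrix <- function(object, ...) {
  s <- summarize_thresholds(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$frequency_khz, y = .data$mean_db)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_db - .data$sd_db,
                                      ymax = .data$mean_db + .data$sd_db),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "frequency (kHz)", y = "threshold (dB SPL)")
}

#' RMS envelope of a neural trace
#'
#' Root-mean-square transform with an exponential time constant: the squared
#' signal is smoothed by a single-pole low-pass filter with time constant
#' `time_constant` (instrument convention), then square-rooted. An alternative
#' sliding-window RMS of the same effective length is selectable.
#'
#' @param x A [trace()].
#' @param time_constant Smoother time constant in seconds (default 0.66 ms);
#'   must exceed one sample interval.
#' @param method `"exponential"` (default) or `"sliding"`.
#' @return A [trace()] of the RMS envelope.
#' @export
rms_envelope <- function(x, time_constant = 0.66e-3,
                         method = c("exponential", "sliding")) {
  stopifnot(inherits(x, "trace"))
  method <- match.arg(method)
  if (time_constant <= 1 / x$sample_rate) {
    abort("`time_constant` must exceed one sample interval.")
  }
  sq <- x$samples^2
  if (method == "exponential") {
    alpha <- exp(-1 / (x$sample_rate * time_constant))
    sm <- as.numeric(signal::filter(signal::Arma(b = 1 - alpha, a = c(1, -alpha)), sq))
  } else {
    k <- max(1L, round(time_constant * x$sample_rate))
    sm <- as.numeric(stats::filter(sq, rep(1 / k, k), sides = 1))
    sm[is.na(sm)] <- cumsum(sq)[is.na(sm)] / seq_len(sum(is.na(sm)))
  }
  trace(sqrt(pmax(sm, 0)), x$sample_rate, unit = x$unit, t0 = x$t0)
}

#' Area under an envelope over a response window
#'
#' Trapezoidal integral of an envelope trace over a fixed window, the measure
#' used to quantify summed auditory-nerve activity (units microvolt-seconds
#' when the envelope is in microvolts).
#'
#' @param envelope A [trace()] (typically from [rms_envelope()]).
#' @param window_start Window start, s (relative to trace t0).
#' @param window_length Window length, s (default 0.475).
#' @return Numeric area (envelope unit x seconds).
#' @export
response_area <- function(envelope, window_start, window_length = 0.475) {
  stopifnot(inherits(envelope, "trace"))
  tt <- trace_times(envelope)
  t1 <- window_start
  t2 <- window_start + window_length
  if (t1 < tt[1] - 1e-12 || t2 > tt[length(tt)] + 1e-12) {
    abort("Response window falls outside the trace.")
  }
  keep <- tt >= t1 & tt <= t2
  ts <- tt[keep]; ys <- envelope$samples[keep]
  # trapezoid over interior samples plus interpolated end points
  y1 <- approx(tt, envelope$samples, t1)$y
  y2 <- approx(tt, envelope$samples, t2)$y
  ts <- c(t1, ts, t2); ys <- c(y1, ys, y2)
  dup <- duplicated(ts)
  ts <- ts[!dup]; ys <- ys[!dup]
  sum(diff(ts) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Percent elevation of the on response above background
#'
#' How much larger the response area during sound is than the equivalent
#' silent-period area: `100 * (on - off) / off`.
#'
#' @param on_area,off_area Response areas (off_area > 0).
#' @return Percent elevation.
#' @examples
#' percent_above_background(62.7, 62.7 / 1.861)  # ~86.1
#' @export
percent_above_background <- function(on_area, off_area) {
  if (any(off_area <= 0)) abort("`off_area` must be positive.")
  100 * (on_area - off_area) / off_area
}

#' Paired t-test of on vs off response areas
#'
#' Standard paired t-test comparing stimulus-on response areas with the
#' equivalent silent-period areas across animals.
#'
#' @param on_areas,off_areas Paired numeric vectors (>= 2 pairs).
#' @return An object of class `"paired_on_off"` wrapping the `htest`, with
#'   [tidy()] and [glance()] methods.
#' @export
paired_on_off_test <- function(on_areas, off_areas) {
  if (length(on_areas) != length(off_areas) || length(on_areas) < 2) {
    abort("Need >= 2 paired on/off areas of equal length.")
  }
  d <- on_areas - off_areas
  if (sd(d) == 0) {
    abort("Zero variance of paired differences; t statistic is undefined.")
  }
  ht <- t.test(on_areas, off_areas, paired = TRUE)
  structure(list(htest = ht, n = length(on_areas),
                 mean_difference = mean(d)),
            class = "paired_on_off")
}

#' @export
print.paired_on_off <- function(x, ...) {
  cat(sprintf("Paired on/off comparison: t = %.4g, df = %d, p = %.4g\n",
              unname(x$htest$statistic), unname(x$htest$parameter),
              x$htest$p.value))
  invisible(x)
}

#' @method tidy paired_on_off
#' @export
tidy.paired_on_off <- function(x, ...) {
  tibble(estimate = unname(x$htest$estimate),
         statistic = unname(x$htest$statistic),
         p.value = x$htest$p.value,
         parameter = unname(x$htest$parameter),
         conf.low = x$htest$conf.int[1],
         conf.high = x$htest$conf.int[2],
         method = "Paired t-test", alternative = x$htest$alternative)
}

#' @method glance paired_on_off
#' @export
glance.paired_on_off <- function(x, ...) {
  tibble(n = x$n, mean_difference = x$mean_difference,
         statistic = unname(x$htest$statistic), p.value = x$htest$p.value)
}
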