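#' Uniformly sampled time-series trace
#'
#' Lightweight container for instrument-style recordings: laser-Doppler
#' displacement or velocity, probe-microphone pressure, or nerve voltage.
#'
#' @param samples Numeric vector of sample values (finite).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param unit Declared sample unit, one of `"m"`, `"m/s"`, `"Pa"`, `"V"`,
#'   `"uV"`, `"nm"` or `""` (arbitrary).
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `"trace"`.
#' @export
trace <- function(samples, sample_rate, unit = "", t0 = 0) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite numeric values.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number.")
  }
  structure(
    list(samples = as.double(samples), sample_rate = as.double(sample_rate),
         unit = as.character(unit), t0 = as.double(t0)),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace: %d samples @ %g Hz, unit '%s', t0 = %g s, duration %.6g s>\n",
              length(x$samples), x$sample_rate, x$unit, x$t0,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' Sample times of a trace
#' @param x A [trace()].
#' @return Numeric vector of times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) / x$sample_rate
}

#' Convert a trace to a tibble
#' @param x A [trace()].
#' @param ... Unused.
#' @return Tibble with columns `time` (s) and `value`.
#' @method as_tibble trace
#' @export
as_tibble.trace <- function(x, ...) {
  tibble(time = trace_times(x), value = x$samples)
}

#' @method autoplot trace
#' @export
autoplot.trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = object$unit)
}

#' Read and write traces as two-column CSV
#'
#' The on-disk format is `time,value` with a uniform time grid; the sampling
#' rate is recovered from the median time step on read.
#'
#' @param x A [trace()].
#' @param path File path.
#' @param unit Declared unit for the samples on read.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a [trace()].
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  write.csv(as_tibble(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, unit = "") {
  df <- read.csv(path)
  if (!all(c("time", "value") %in% names(df))) {
    abort("Trace CSV must have columns `time` and `value`.")
  }
  dt <- diff(df$time)
  if (length(dt) < 1 || any(dt <= 0)) abort("Trace CSV times must increase.")
  if (max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt)) {
    warn("Trace CSV time grid is not perfectly uniform; using median step.")
  }
  trace(df$value, sample_rate = 1 / stats::median(dt), unit = unit,
        t0 = df$time[1])
}

#' Read and write traces as WAV files
#'
#' Minimal RIFF/WAVE support (mono, 16-bit PCM or 32-bit IEEE float) so traces
#' can round-trip through the common instrument export format. Values are
#' stored unscaled for float WAVs; 16-bit files are normalised to full scale on
#' write and returned in [-1, 1] on read.
#'
#' @param x A [trace()].
#' @param path File path.
#' @param bits 16 (PCM) or 32 (IEEE float; default).
#' @param unit Declared unit on read.
#' @return `write_trace_wav` returns `path` invisibly; `read_trace_wav` a
#'   [trace()].
#' @export
write_trace_wav <- function(x, path, bits = 32) {
  stopifnot(inherits(x, "trace"), bits %in% c(16L, 32L))
  fs <- round(x$sample_rate)
  n <- length(x$samples)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_tag <- if (bits == 32) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")               # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(x$samples, con, size = 4, endian = "little")
  } else {
    peak <- max(abs(x$samples), 1e-12)
    writeBin(as.integer(round(x$samples / peak * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_trace_wav
#' @export
read_trace_wav <- function(path, unit = "") {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") abort("Not a RIFF/WAVE file.")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") abort("Not a RIFF/WAVE file.")
  fmt_tag <- NULL; fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, integer(), size = 2, endian = "little")
      nchan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (nchan != 1) abort("Only mono WAV files are supported.")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (id == "data") {
      if (is.null(bits)) abort("WAV data chunk before fmt chunk.")
      if (bits == 32 && fmt_tag == 3) {
        samples <- readBin(con, numeric(), n = size / 4, size = 4,
                           endian = "little")
      } else if (bits == 16 && fmt_tag == 1) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           signed = TRUE, endian = "little") / 32768
      } else {
        abort("Only 16-bit PCM or 32-bit float WAV is supported.")
      }
    } else {
      invisible(readBin(con, raw(), n = size))
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) abort("WAV file has no data chunk.")
  trace(samples, sample_rate = fs, unit = unit)
}
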