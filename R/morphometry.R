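#' Equivalent circular radius of a slit opening
#'
#' The slit entrance of a pinnal cavity is treated as a perfect circle of the
#' same area, giving the opening radius used by the neckless Helmholtz
#' resonance formula.
#'
#' Unit handling: the radius comes back in the length unit implied by the
#' square root of the area unit (mm^2 in, mm out; m^2 in, m out). No conversion
#' is performed here.
#'
#' @param area Numeric vector of opening areas, strictly positive.
#' @return Numeric vector of radii, `sqrt(area / pi)`.
#' @examples
#' equivalent_slit_radius(pi)    # 1
#' equivalent_slit_radius(0.16)  # 0.2257 (mm if area was mm^2)
#' @export
equivalent_slit_radius <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    abort("`area` must be finite and strictly positive.")
  }
  sqrt(area / pi)
}

#' Neckless Helmholtz resonance frequency (scalar core)
#'
#' Resonance of a cavity of volume `V` opened by a neckless circular aperture
#' of radius `r`, with the aperture end-correction folded into a single factor:
#' \deqn{f_h = \frac{c}{2\pi}\sqrt{\frac{\lambda\, r}{V}}}
#' where `lambda` is the end-correction factor (default 1.85) that stands in
#' for the effective neck length of the open slit.
#'
#' All arguments are SI (m, m^3, m/s). Use [helmholtz_resonance()] for the
#' data-frame interface with mm-based morphometry.
#'
#' @param radius_m Aperture radius in metres (> 0).
#' @param volume_m3 Cavity volume in cubic metres (> 0).
#' @param speed_of_sound Speed of sound in m/s (default 343).
#' @param end_correction Dimensionless end-correction factor (default 1.85).
#' @return Resonance frequency in Hz.
#' @examples
#' r <- equivalent_slit_radius(0.16e-6)        # m, from 0.16 mm^2
#' helmholtz_frequency(r, 0.14e-9) / 1000      # ~94.27 kHz
#' @export
helmholtz_frequency <- function(radius_m, volume_m3, speed_of_sound = 343,
                                end_correction = 1.85) {
  stopifnot(is.numeric(radius_m), is.numeric(volume_m3))
  if (any(!is.finite(radius_m)) || any(radius_m <= 0)) {
    abort("`radius_m` must be finite and strictly positive.")
  }
  if (any(!is.finite(volume_m3)) || any(volume_m3 <= 0)) {
    abort("`volume_m3` must be finite and strictly positive.")
  }
  if (speed_of_sound <= 0) abort("`speed_of_sound` must be positive.")
  if (end_correction <= 0) abort("`end_correction` must be positive.")
  (speed_of_sound / (2 * pi)) * sqrt(end_correction * radius_m / volume_m3)
}

#' Cavity morphometry table
#'
#' Validating constructor for the tidy morphometry schema used throughout the
#' package: one row per pinnal cavity with slit area (mm^2) and cavity volume
#' (mm^3), plus optional ancillary lengths.
#'
#' @param slit_area_mm2 Slit entrance areas in mm^2 (> 0).
#' @param cavity_volume_mm3 Cavity volumes in mm^3 (> 0).
#' @param label Cavity labels (e.g. `"APC"`, `"PPC"`); recycled.
#' @param pinna_protrusion_mm,septum_width_mm Optional lengths in mm (>= 0).
#' @return A tibble with columns `label`, `slit_area_mm2`, `cavity_volume_mm3`
#'   and any supplied optional columns.
#' @export
cavity_morphometry <- function(slit_area_mm2, cavity_volume_mm3,
                               label = "cavity",
                               pinna_protrusion_mm = NULL,
                               septum_width_mm = NULL) {
  if (any(!is.finite(slit_area_mm2)) || any(slit_area_mm2 <= 0)) {
    abort("`slit_area_mm2` must be finite and strictly positive.")
  }
  if (any(!is.finite(cavity_volume_mm3)) || any(cavity_volume_mm3 <= 0)) {
    abort("`cavity_volume_mm3` must be finite and strictly positive.")
  }
  out <- tibble(
    label = rep_len(as.character(label), length(slit_area_mm2)),
    slit_area_mm2 = as.double(slit_area_mm2),
    cavity_volume_mm3 = as.double(cavity_volume_mm3)
  )
  for (nm in c("pinna_protrusion_mm", "septum_width_mm")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (any(v < 0, na.rm = TRUE)) abort(sprintf("`%s` must be >= 0.", nm))
      out[[nm]] <- as.double(v)
    }
  }
  out
}

#' Predict pinnal cavity resonances from morphometry
#'
#' Applies the neckless Helmholtz model to each row of a morphometry table:
#' the slit is converted to an equivalent circular radius, units are converted
#' to SI, and the resonance frequency is evaluated with the configured
#' end-correction factor.
#'
#' @param data A data frame with columns `slit_area_mm2` and
#'   `cavity_volume_mm3` (see [cavity_morphometry()]), or one produced by
#'   [read_morphometry()].
#' @param speed_of_sound Speed of sound in air, m/s (default 343).
#' @param end_correction End-correction factor (default 1.85).
#' @return The input as a tibble with added columns `equivalent_radius_m`,
#'   `resonance_hz` and `resonance_khz` (class `"resonance_prediction"`).
#' @examples
#' morph <- cavity_morphometry(c(0.16, 0.16), c(0.14, 0.15), c("APC", "PPC"))
#' helmholtz_resonance(morph)
#' @export
helmholtz_resonance <- function(data, speed_of_sound = 343,
                                end_correction = 1.85) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (see `cavity_morphometry()`).")
  }
  need <- c("slit_area_mm2", "cavity_volume_mm3")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)
  r_m <- equivalent_slit_radius(out$slit_area_mm2 * 1e-6)     # mm^2 -> m^2
  v_m3 <- out$cavity_volume_mm3 * 1e-9                        # mm^3 -> m^3
  if (any(v_m3 <= 0)) abort("cavity volumes must be positive.")
  f <- helmholtz_frequency(r_m, v_m3, speed_of_sound, end_correction)
  out$equivalent_radius_m <- r_m
  out$resonance_hz <- f
  out$resonance_khz <- f / 1000
  attr(out, "speed_of_sound") <- speed_of_sound
  attr(out, "end_correction") <- end_correction
  class(out) <- c("resonance_prediction", class(out))
  out
}

#' @method glance resonance_prediction
#' @export
glance.resonance_prediction <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_resonance_khz = mean(x$resonance_khz),
    sd_resonance_khz = if (nrow(x) > 1) sd(x$resonance_khz) else NA_real_,
    speed_of_sound = attr(x, "speed_of_sound"),
    end_correction = attr(x, "end_correction")
  )
}

#' @method tidy resonance_prediction
#' @export
tidy.resonance_prediction <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Read a morphometry table from CSV
#'
#' Expects the tidy schema of [cavity_morphometry()]: columns `label`,
#' `slit_area_mm2`, `cavity_volume_mm3` and optional ancillary lengths.
#'
#' @param path Path to a CSV file.
#' @return A validated morphometry tibble.
#' @export
read_morphometry <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", "slit_area_mm2", "cavity_volume_mm3")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf(
      "Malformed morphometry CSV: missing %s. Expected columns: %s.",
      paste(missing_cols, collapse = ", "), paste(need, collapse = ", ")
    ))
  }
  cavity_morphometry(
    slit_area_mm2 = df$slit_area_mm2,
    cavity_volume_mm3 = df$cavity_volume_mm3,
    label = df$label,
    pinna_protrusion_mm = df[["pinna_protrusion_mm"]],
    septum_width_mm = df[["septum_width_mm"]]
  )
}
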