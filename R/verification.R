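## Verification against spectrometry: sweep one NDVI band across a
## wavelength range and find the wavelength at which spectrometer NDVI
## best matches the camera's NDVI.

#' Wavelength sweep against spectrometer NDVI
#'
#' For each candidate wavelength, computes per-sample NDVI from the
#' spectra with the swept band at that wavelength and the other band held
#' fixed, then the mean absolute percentage difference from the camera
#' NDVI values: `mean(100 * |NDVI_cam - NDVI_spec| / |NDVI_spec|)`.  The
#' best wavelength attains the minimum (ties break toward the shortest
#' wavelength).  Samples where the spectrometer NDVI is zero at a
#' candidate wavelength are excluded there with a warning.
#'
#' @param camera_ndvi Numeric vector of per-sample camera NDVI.
#' @param spectra List of per-sample [spectral_curve()]s, same order.
#' @param swept_band `"red"` or `"nir"` -- which band is swept.
#' @param sweep_range Wavelength range `c(from, to)` in nm
#'   (default 600--700 for red, use 700--800 for NIR).
#' @param step Sweep step in nm, endpoint inclusive (default 10; 1 nm for
#'   fine sweeps).
#' @param fixed_wavelength The fixed band's wavelength in nm (default:
#'   750 when sweeping red, 620 when sweeping NIR).
#' @return An object of class `sweep_result`: `swept_band`,
#'   `wavelengths`, `mean_abs_pct_diff`, `best_wavelength`.
#' @export
wavelength_sweep <- function(camera_ndvi, spectra,
                             swept_band = c("red", "nir"),
                             sweep_range = if (swept_band == "red")
                               c(600, 700) else c(700, 800),
                             step = 10,
                             fixed_wavelength = if (swept_band == "red")
                               750 else 620) {
  swept_band <- match.arg(swept_band)
  stopifnot(length(camera_ndvi) >= 1L,
            length(spectra) == length(camera_ndvi),
            length(sweep_range) == 2L, sweep_range[1] < sweep_range[2],
            step > 0)
  wavelengths <- seq(sweep_range[1], sweep_range[2], by = step)
  if (wavelengths[length(wavelengths)] < sweep_range[2]) {
    wavelengths <- c(wavelengths, sweep_range[2])
  }
  r_fixed <- vapply(spectra, .curve_at, numeric(1), grid = fixed_wavelength)
  if (anyNA(r_fixed)) stop("spectra do not cover the fixed wavelength")
  pct <- vapply(wavelengths, function(wl) {
    r_sweep <- vapply(spectra, .curve_at, numeric(1), grid = wl)
    if (anyNA(r_sweep)) stop("spectra do not cover the sweep range")
    ndvi_spec <- if (swept_band == "red") {
      ndvi_value(r_fixed, r_sweep)
    } else {
      ndvi_value(r_sweep, r_fixed)
    }
    keep <- !is.na(ndvi_spec) & ndvi_spec != 0
    if (!any(keep)) {
      stop(sprintf(
        "degenerate sweep: spectrometer NDVI is zero for all samples at %g nm",
        wl))
    }
    if (!all(keep)) {
      warning(sprintf(
        "%d sample(s) excluded at %g nm (spectrometer NDVI is zero)",
        sum(!keep), wl))
    }
    mean(100 * abs(camera_ndvi[keep] - ndvi_spec[keep]) /
           abs(ndvi_spec[keep]))
  }, numeric(1))
  structure(list(
    swept_band = swept_band,
    wavelengths = wavelengths,
    mean_abs_pct_diff = pct,
    best_wavelength = wavelengths[which.min(pct)],
    fixed_wavelength = fixed_wavelength
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %s band swept %g-%g nm (fixed %g nm)\n  best wavelength: %g nm (mean |%% diff| %.3f)\n",
    x$swept_band, min(x$wavelengths), max(x$wavelengths),
    x$fixed_wavelength, x$best_wavelength, min(x$mean_abs_pct_diff)))
  invisible(x)
}

#' @rdname wavelength_sweep
#' @param x A `sweep_result`.
#' @param path Output CSV path (columns `wavelength_nm`,
#'   `mean_abs_pct_diff`).
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "sweep_result"))
  utils::write.csv(
    data.frame(wavelength_nm = x$wavelengths,
               mean_abs_pct_diff = x$mean_abs_pct_diff),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Agreement between camera and reference NDVI
#'
#' Ordinary least squares of the camera values on the reference values:
#' returns the squared Pearson correlation, slope, intercept, and the
#' population standard deviation of the per-sample differences
#' (camera - reference).
#'
#' @param camera_vals,reference_vals Numeric vectors of equal length
#'   (>= 3).
#' @return List with `r2`, `slope`, `intercept`, `sd_diff`.
#' @export
compare_to_reference <- function(camera_vals, reference_vals) {
  stopifnot(is.numeric(camera_vals), is.numeric(reference_vals),
            length(camera_vals) == length(reference_vals),
            length(camera_vals) >= 3L)
  if (stats::var(reference_vals) == 0) {
    stop("degenerate regression: zero variance in the reference values")
  }
  fit <- stats::lm(camera_vals ~ reference_vals)
  d <- camera_vals - reference_vals
  list(
    r2 = unname(stats::cor(camera_vals, reference_vals)^2),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    sd_diff = sqrt(mean((d - mean(d))^2))
  )
}
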