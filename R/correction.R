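## Red-leak correction: the plastic filter in front of the NIR camera
## transmits a small fraction (5-15%) of red light, which additively
## contaminates the measured NIR signal.

#' Spectral curve
#'
#' A sampled function of wavelength, e.g. filter transmission,
#' illumination, or reflectance spectra.
#'
#' @param wavelength_nm Wavelengths in nm, strictly increasing.
#' @param value Curve values at those wavelengths.
#' @return A data frame of class `spectral_curve` with columns
#'   `wavelength_nm`, `value`.
#' @export
spectral_curve <- function(wavelength_nm, value) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(value),
            length(wavelength_nm) == length(value),
            length(wavelength_nm) >= 2L,
            all(is.finite(wavelength_nm)), all(diff(wavelength_nm) > 0))
  structure(data.frame(wavelength_nm = wavelength_nm, value = value),
            class = c("spectral_curve", "data.frame"))
}

#' @rdname spectral_curve
#' @param path CSV file with columns `wavelength_nm`, `value`.
#' @export
read_spectral_curve <- function(path) {
  d <- utils::read.csv(path)
  spectral_curve(d$wavelength_nm, d$value)
}

## Interpolate a curve onto a wavelength grid.  rule = 1: NA outside
## the sampled support.
.curve_at <- function(curve, grid) {
  stats::approx(curve$wavelength_nm, curve$value, xout = grid, rule = 1)$y
}

#' Leak model
#'
#' @param fraction Share `f` of the red-band reflectance signal that
#'   additively contaminates the measured NIR reflectance, in \[0, 1).
#' @return An object of class `leak_model`.
#' @export
leak_model <- function(fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            is.finite(fraction), fraction >= 0, fraction < 1)
  structure(list(fraction = fraction), class = "leak_model")
}

#' Estimate the red-leak fraction from spectral curves
#'
#' Integrates illumination x typical reflectance x filter transmission
#' over the red and NIR bands (centre +/- fwhm/2, on a common 1 nm grid
#' covering 400--900 nm) and returns
#' `f = S_red / (S_red + S_nir)` -- the share of the filtered camera's
#' signal that originates in the red band.
#'
#' @param filter_transmission A [spectral_curve()] of filter transmission
#'   (0--1 or percent; units cancel).
#' @param red_band,nir_band [band_definition()]s.  A `fwhm` of 0 falls
#'   back to a 10 nm integration window.
#' @param illumination Optional [spectral_curve()]; flat if `NULL`.
#' @param typical_reflectance Optional [spectral_curve()]; flat if `NULL`.
#' @return A [leak_model()].
#' @export
estimate_leak_fraction <- function(filter_transmission,
                                   red_band = band_definition("red", 620),
                                   nir_band = band_definition("nir", 750),
                                   illumination = NULL,
                                   typical_reflectance = NULL) {
  grid <- 400:900
  tr <- .curve_at(filter_transmission, grid)
  il <- if (is.null(illumination)) rep(1, length(grid))
        else .curve_at(illumination, grid)
  re <- if (is.null(typical_reflectance)) rep(1, length(grid))
        else .curve_at(typical_reflectance, grid)
  band_signal <- function(band) {
    half <- if (band$fwhm > 0) band$fwhm / 2 else 5
    sel <- grid >= band$center_wavelength - half &
           grid <= band$center_wavelength + half
    v <- il[sel] * re[sel] * tr[sel]
    if (anyNA(v)) stop("spectral curves do not cover the band ",
                       band$name)
    sum(v)
  }
  s_red <- band_signal(red_band)
  s_nir <- band_signal(nir_band)
  if (s_red + s_nir <= 0) stop("degenerate signal: zero total band energy")
  leak_model(s_red / (s_red + s_nir))
}

#' Remove the red leak from a measured NIR reflectance image
#'
#' `nir_corr = nir_meas - f * red`, clamped at 0 with clamped pixels
#' flagged.  With `f = 0` the input is returned unchanged.  Inputs must be
#' co-registered.  Without correction, the leak biases NDVI upward at low
#' NDVI (extra signal on the NIR channel).
#'
#' @param nir_meas Measured NIR [reflectance_image()] (leak included).
#' @param red Co-registered red [reflectance_image()].
#' @param leak A [leak_model()] or bare fraction.
#' @return A corrected [reflectance_image()].
#' @export
correct_nir_leak <- function(nir_meas, red, leak) {
  stopifnot(inherits(nir_meas, "reflectance_image"),
            inherits(red, "reflectance_image"))
  f <- if (inherits(leak, "leak_model")) leak$fraction else leak
  stopifnot(is.numeric(f), length(f) == 1L, f >= 0, f < 1)
  if (!identical(dim(nir_meas$values), dim(red$values))) {
    stop("dimension mismatch between NIR and red images")
  }
  if (f == 0) return(nir_meas)
  v <- nir_meas$values - f * red$values
  clamped <- nir_meas$clamped | (v < 0)
  v <- pmax(v, 0)
  reflectance_image(v, nir_meas$band, nir_meas$mask & red$mask, clamped)
}
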