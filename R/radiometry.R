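#' Spectral band definition
#'
#' A band is described by a text label, a centre wavelength and a full width
#' at half maximum (FWHM).  `fwhm = 0` denotes an idealised monochromatic
#' band, as used for simulated spectrometer samples.
#'
#' @param name Text label, e.g. `"red"`.
#' @param center_wavelength Centre wavelength in nm; must lie in
#'   \[400, 1000\].
#' @param fwhm Full width at half maximum in nm; must be >= 0.
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("red", 620)
#' band_definition("nir", 750, fwhm = 40)
#' @export
band_definition <- function(name, center_wavelength, fwhm = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(center_wavelength) || length(center_wavelength) != 1L ||
      !is.finite(center_wavelength) ||
      center_wavelength < 400 || center_wavelength > 1000) {
    stop("center_wavelength must be a single value in [400, 1000] nm")
  }
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm < 0) {
    stop("fwhm must be a single non-negative value (nm)")
  }
  structure(
    list(name = name, center_wavelength = as.numeric(center_wavelength),
         fwhm = as.numeric(fwhm)),
    class = "band_definition"
  )
}

#' Standard band sets
#'
#' Band centres used by the two-camera rig (red channel of an RGB camera at
#' 620 nm, filtered NIR camera at 750 nm) and by the Micasense RedEdge
#' narrowband cameras (red 668 nm FWHM 10, red-edge 717 nm FWHM 10,
#' NIR 840 nm FWHM 40), which give two alternative NDVI band pairings.
#'
#' @return A named list of `band_definition` objects.
#' @export
standard_bands <- function() {
  list(
    pi_red        = band_definition("red", 620),
    pi_nir        = band_definition("nir", 750),
    micasense_red = band_definition("red", 668, fwhm = 10),
    micasense_rededge = band_definition("rededge", 717, fwhm = 10),
    micasense_nir = band_definition("nir", 840, fwhm = 40)
  )
}

#' Camera capture settings
#'
#' @param iso ISO sensitivity (dimensionless, > 0).
#' @param shutter_speed Shutter speed in microseconds (> 0).
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(iso = 400, shutter_speed = 2500) {
  stopifnot(is.numeric(iso), length(iso) == 1L, is.finite(iso), iso > 0,
            is.numeric(shutter_speed), length(shutter_speed) == 1L,
            is.finite(shutter_speed), shutter_speed > 0)
  structure(list(iso = as.numeric(iso),
                 shutter_speed = as.numeric(shutter_speed)),
            class = "camera_config")
}

#' 8-bit multi-channel camera frame
#'
#' Pixels are stored as an `h x w x nchannel` integer array of digital
#' numbers (DN) in \[0, 255\].  A plain matrix is promoted to a single
#' channel.
#'
#' @param pixels Matrix or 3-d array of DNs in \[0, 255\].
#' @param channels Character vector of band labels, one per channel.
#' @param camera_role `"red-cam"` or `"nir-cam"`.
#' @param settings A [camera_config()].
#' @return An object of class `digital_image`.
#' @export
digital_image <- function(pixels, channels = "red",
                          camera_role = c("red-cam", "nir-cam"),
                          settings = camera_config()) {
  camera_role <- match.arg(camera_role)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must be at least 1 x 1")
  }
  if (length(channels) != dim(pixels)[3]) {
    stop("length(channels) must match the number of channels")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != round(pixels))) {
    stop("all digital numbers must be integers in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  stopifnot(inherits(settings, "camera_config"))
  structure(list(pixels = pixels, channels = as.character(channels),
                 camera_role = camera_role, settings = settings),
            class = "digital_image")
}

#' @export
print.digital_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<digital_image> %d x %d, channels: %s, role: %s\n",
              d[1], d[2], paste(x$channels, collapse = ", "), x$camera_role))
  invisible(x)
}

## Extract one channel as a DN matrix.
image_channel <- function(img, channel) {
  stopifnot(inherits(img, "digital_image"))
  i <- match(channel, img$channels)
  if (is.na(i)) stop(sprintf("channel '%s' not present in image", channel))
  img$pixels[, , i]
}

#' Single-band relative reflectance image
#'
#' Values are relative reflectance in percent, nominally in \[0, 100\]
#' (the encoder saturates values outside that range).  `mask` holds
#' per-pixel validity flags (`TRUE` = valid); undefined pixels are marked
#' invalid by the operations that produce them.  `clamped` records pixels
#' whose value was saturated onto the \[0, 100\] range.
#'
#' @param values Numeric matrix of reflectance percent.
#' @param band A [band_definition()].
#' @param mask Logical matrix of validity flags; defaults to finite values.
#' @param clamped Logical matrix marking clamped pixels (optional).
#' @return An object of class `reflectance_image`.
#' @export
reflectance_image <- function(values, band, mask = NULL, clamped = NULL) {
  stopifnot(is.matrix(values), inherits(band, "band_definition"))
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(is.logical(mask), identical(dim(mask), dim(values)))
  if (is.null(clamped)) clamped <- matrix(FALSE, nrow(values), ncol(values))
  stopifnot(is.logical(clamped), identical(dim(clamped), dim(values)))
  structure(list(values = values, band = band, mask = mask, clamped = clamped),
            class = "reflectance_image")
}

#' @export
print.reflectance_image <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<reflectance_image> %d x %d, band %s (%g nm), %d/%d valid, range [%.2f, %.2f]%%\n",
    nrow(x$values), ncol(x$values), x$band$name, x$band$center_wavelength,
    sum(x$mask), length(x$mask),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' 16-bit encoding specification
#'
#' Reflectance 0--100% maps linearly onto codes 0--`scale_denominator`;
#' NDVI -1..+1 maps onto the same code range.  Stored codes saturate at
#' `max_code` (65535, the largest unsigned 16-bit value) while the pure
#' decode formula keeps the nominal denominator 65536 so that code 65536
#' decodes exactly to 100% / NDVI +1.
#'
#' @param scale_denominator Integer scale, default 65536.
#' @param max_code Largest storable code, default 65535.
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(scale_denominator = 65536L, max_code = 65535L) {
  stopifnot(is.numeric(scale_denominator), is.numeric(max_code))
  scale_denominator <- as.integer(scale_denominator)
  max_code <- as.integer(max_code)
  if (!(max_code > 0L && max_code < scale_denominator &&
        scale_denominator <= 65536L)) {
    stop("require 0 < max_code < scale_denominator <= 65536")
  }
  structure(list(scale_denominator = scale_denominator, max_code = max_code,
                 rounding = "half-away-from-zero"),
            class = "encoding_spec")
}

#' Encoded 16-bit image
#'
#' @param codes Integer matrix of codes in \[0, max_code\].
#' @param payload `"reflectance"` or `"ndvi"`.
#' @param spec An [encoding_spec()].
#' @param mask Logical validity matrix (TRUE = valid).
#' @param band Optional band metadata (a [band_definition()] or list).
#' @return An object of class `encoded_image`.
#' @export
encoded_image <- function(codes, payload = c("reflectance", "ndvi"),
                          spec = encoding_spec(), mask = NULL, band = NULL) {
  payload <- match.arg(payload)
  stopifnot(is.matrix(codes), inherits(spec, "encoding_spec"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(codes), ncol(codes))
  stopifnot(is.logical(mask), identical(dim(mask), dim(codes)))
  if (anyNA(codes) || any(codes < 0L) || any(codes > spec$max_code)) {
    stop("codes must lie in [0, max_code]")
  }
  storage.mode(codes) <- "integer"
  structure(list(codes = codes, payload = payload, spec = spec, mask = mask,
                 band = band),
            class = "encoded_image")
}

#' @export
print.encoded_image <- function(x, ...) {
  cat(sprintf("<encoded_image> %d x %d, payload %s, codes [%d, %d], %d/%d valid\n",
              nrow(x$codes), ncol(x$codes), x$payload,
              min(x$codes), max(x$codes), sum(x$mask), length(x$mask)))
  invisible(x)
}

## Deterministic half-away-from-zero rounding (round() rounds half-to-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Encode a reflectance image to 16-bit codes
#'
#' `code = round(v / 100 * scale_denominator)` with half-away-from-zero
#' rounding, saturated onto \[0, max_code\].  Masked pixels encode 0 and
#' stay flagged in the output mask.
#'
#' @param img A [reflectance_image()].
#' @param spec An [encoding_spec()].
#' @return An [encoded_image()] with payload `"reflectance"`.
#' @examples
#' b <- band_definition("red", 620)
#' r <- reflectance_image(matrix(50, 2, 2), b)
#' encode_reflectance(r)$codes[1, 1]  # 32768
#' @export
encode_reflectance <- function(img, spec = encoding_spec()) {
  stopifnot(inherits(img, "reflectance_image"), inherits(spec, "encoding_spec"))
  v <- img$values
  bad <- !is.finite(v) & img$mask
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite unmasked reflectance at pixel (row %d, col %d)",
                 ij[1], ij[2]))
  }
  codes <- round_half_away(v / 100 * spec$scale_denominator)
  codes[!img$mask] <- 0
  codes <- pmin(pmax(codes, 0), spec$max_code)
  codes <- matrix(as.integer(codes), nrow(v), ncol(v))
  encoded_image(codes, "reflectance", spec, img$mask, img$band)
}

#' Decode a 16-bit reflectance image
#'
#' Inverse of [encode_reflectance()]: `v = code * 100 / scale_denominator`.
#' Round-trip error is at most one code width (100/65536 percent).
#'
#' @param enc An [encoded_image()] with payload `"reflectance"`.
#' @return A [reflectance_image()].
#' @export
decode_reflectance <- function(enc) {
  stopifnot(inherits(enc, "encoded_image"))
  if (enc$payload != "reflectance") {
    stop("payload mismatch: expected 'reflectance', got '", enc$payload, "'")
  }
  v <- enc$codes * 100 / enc$spec$scale_denominator
  band <- enc$band
  if (!inherits(band, "band_definition")) band <- band_definition("band", 620)
  reflectance_image(v, band, enc$mask)
}

#' Pixel-wise NDVI from reflectance
#'
#' `(nir - red) / (nir + red)` with both inputs as reflectance percent in
#' \[0, 100\].  Pixels with `nir + red <= eps` are undefined and returned
#' as `NA` for the caller to mask.
#'
#' @param nir,red Numeric vectors/matrices of reflectance percent (>= 0).
#' @param eps Undefined-pixel threshold on `nir + red`, percent.
#' @return NDVI values in \[-1, 1\], `NA` where undefined.
#' @examples
#' ndvi_value(39.40, 25.53)  # 0.2136 (Burgundy panel material)
#' @export
ndvi_value <- function(nir, red, eps = 1e-6) {
  if (any(nir[is.finite(nir)] < 0) || any(red[is.finite(red)] < 0)) {
    stop("reflectance inputs must be non-negative")
  }
  s <- nir + red
  out <- (nir - red) / s
  out[!is.finite(s) | s <= eps] <- NA_real_
  out
}

#' Encode an NDVI grid to 16-bit codes
#'
#' NDVI -1..+1 maps linearly onto codes 0..`scale_denominator`:
#' `code = round((v + 1) / 2 * scale_denominator)`, saturated onto
#' \[0, max_code\].  `NA` values are treated as masked.
#'
#' @param values Numeric matrix of NDVI in \[-1, 1\] (or masked).
#' @param spec An [encoding_spec()].
#' @param mask Logical validity matrix; defaults to finite values.
#' @param band Optional band metadata.
#' @return An [encoded_image()] with payload `"ndvi"`.
#' @export
encode_ndvi <- function(values, spec = encoding_spec(), mask = NULL,
                        band = NULL) {
  stopifnot(is.matrix(values), inherits(spec, "encoding_spec"))
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(is.logical(mask), identical(dim(mask), dim(values)))
  mask <- mask & is.finite(values)
  bad <- !is.finite(values) & mask
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite unmasked NDVI at pixel (row %d, col %d)",
                 ij[1], ij[2]))
  }
  codes <- round_half_away((values + 1) / 2 * spec$scale_denominator)
  codes[!mask] <- 0
  codes <- pmin(pmax(codes, 0), spec$max_code)
  codes <- matrix(as.integer(codes), nrow(values), ncol(values))
  encoded_image(codes, "ndvi", spec, mask, band)
}

#' Decode 16-bit codes to NDVI
#'
#' The exact inverse scaling `NDVI = code * (2 / 65536) - 1`.  Accepts the
#' nominal endpoint 65536 (which decodes to exactly +1) even though stored
#' codes saturate at 65535.  Given an [encoded_image()], returns a numeric
#' matrix with `NA` at masked pixels.
#'
#' @param code Integer codes in \[0, 65536\], or an [encoded_image()] with
#'   payload `"ndvi"`.
#' @param spec An [encoding_spec()] (ignored when `code` is an
#'   `encoded_image`).
#' @return NDVI values in \[-1, 1\].
#' @examples
#' decode_ndvi(65536)  # +1
#' decode_ndvi(0)      # -1
#' @export
decode_ndvi <- function(code, spec = encoding_spec()) {
  if (inherits(code, "encoded_image")) {
    if (code$payload != "ndvi") {
      stop("payload mismatch: expected 'ndvi', got '", code$payload, "'")
    }
    v <- code$codes * (2 / code$spec$scale_denominator) - 1
    v[!code$mask] <- NA_real_
    return(v)
  }
  stopifnot(is.numeric(code))
  if (anyNA(code) || any(code < 0 | code > spec$scale_denominator)) {
    stop(sprintf("codes must lie in [0, %d]", spec$scale_denominator))
  }
  code * (2 / spec$scale_denominator) - 1
}
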