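## NDVI image construction, region statistics and display colorization.

#' Build an encoded NDVI image from a band pair
#'
#' Computes `(NIR - RED) / (NIR + RED)` per pixel from co-registered
#' reflectance images and encodes the result to 16 bits (-1..+1 mapped
#' onto 0..65536).  The output mask is the union of the input masks plus
#' pixels where NDVI is undefined (`nir + red` below threshold).
#'
#' @param red,nir Co-registered [reflectance_image()]s of equal size.
#' @param spec An [encoding_spec()].
#' @return An [encoded_image()] with payload `"ndvi"`; band metadata
#'   records both input bands.
#' @examples
#' b <- standard_bands()
#' red <- reflectance_image(matrix(25.53, 2, 2), b$pi_red)
#' nir <- reflectance_image(matrix(39.40, 2, 2), b$pi_nir)
#' build_ndvi_image(red, nir)$codes[1, 1]  # 39768
#' @export
build_ndvi_image <- function(red, nir, spec = encoding_spec()) {
  stopifnot(inherits(red, "reflectance_image"),
            inherits(nir, "reflectance_image"))
  if (!identical(dim(red$values), dim(nir$values))) {
    stop("dimension mismatch between red and NIR images")
  }
  v <- ndvi_value(nir$values, red$values)
  mask <- red$mask & nir$mask & !is.na(v)
  v[is.na(v)] <- 0
  encode_ndvi(v, spec, mask,
              band = list(red = red$band, nir = nir$band))
}

#' Descriptive statistics of an NDVI region
#'
#' Mean, population standard deviation, coefficient of variation
#' (sd/mean, `NA` when |mean| is below 1e-12) and Fisher-Pearson skewness
#' `g1 = m3 / m2^(3/2)` (0 for zero-variance regions) over the pixels of a
#' region of interest.  Masked (`NA`) pixels are excluded.
#'
#' @param ndvi Numeric matrix of decoded NDVI values (`NA` = masked), or
#'   an [encoded_image()] with payload `"ndvi"`.
#' @param roi Either a 0-based half-open rectangle
#'   `c(row0, col0, height, width)` or a logical mask matrix; `NULL` uses
#'   the whole image.
#' @return An object of class `region_stats`: list with `mean`, `sd`,
#'   `cov`, `skewness`, `n`.
#' @export
region_stats <- function(ndvi, roi = NULL) {
  if (inherits(ndvi, "encoded_image")) ndvi <- decode_ndvi(ndvi)
  stopifnot(is.matrix(ndvi))
  if (is.null(roi)) {
    x <- as.vector(ndvi)
  } else if (is.logical(roi)) {
    stopifnot(identical(dim(roi), dim(ndvi)))
    x <- ndvi[roi]
  } else {
    stopifnot(is.numeric(roi), length(roi) == 4L)
    r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
    if (r0 < 0 || c0 < 0 || h < 1 || w < 1 ||
        r0 + h > nrow(ndvi) || c0 + w > ncol(ndvi)) {
      stop("ROI lies outside the image")
    }
    x <- ndvi[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)]
  }
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty region: no unmasked pixels in ROI")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  structure(list(
    mean = mu,
    sd = sqrt(m2),
    cov = if (abs(mu) < 1e-12) NA_real_ else sqrt(m2) / mu,
    skewness = if (m2 == 0) 0 else m3 / m2^1.5,
    n = n
  ), class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf(
    "<region_stats> n = %d, mean = %.4f, sd = %.4f, cov = %s, skewness = %.4f\n",
    x$n, x$mean, x$sd,
    if (is.na(x$cov)) "NA" else sprintf("%.4f", x$cov), x$skewness))
  invisible(x)
}

.luts <- function() {
  list(
    ## low NDVI (code 0) -> red, high NDVI -> dark green
    green_red = grDevices::colorRampPalette(
      c("#67001F", "#D6604D", "#F4A582", "#FDDBC7", "#D9F0D3",
        "#A6DBA0", "#5AAE61", "#1B7837"))(256),
    grayscale = grDevices::gray(seq(0, 1, length.out = 256))
  )
}

#' Colorize an encoded NDVI image for display
#'
#' Maps codes through a named 256-entry look-up table (nearest entry on
#' `code %/% 256`); masked pixels render black.  Output is deterministic:
#' the same input and LUT always yield byte-identical arrays.
#'
#' @param enc An [encoded_image()] with payload `"ndvi"`.
#' @param lut_name `"green_red"` (default, diverging green-to-red with
#'   high NDVI green) or `"grayscale"`.
#' @return An `h x w x 3` numeric array of RGB values in \[0, 1\].
#' @export
colorize <- function(enc, lut_name = "green_red") {
  stopifnot(inherits(enc, "encoded_image"))
  if (enc$payload != "ndvi") stop("colorize expects an NDVI payload")
  luts <- .luts()
  if (!lut_name %in% names(luts)) {
    stop(sprintf("unknown LUT '%s'; available: %s", lut_name,
                 paste(names(luts), collapse = ", ")))
  }
  lut <- grDevices::col2rgb(luts[[lut_name]]) / 255
  idx <- pmin(enc$codes %/% 256L, 255L) + 1L
  h <- nrow(enc$codes); w <- ncol(enc$codes)
  out <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    ch <- matrix(lut[k, idx], h, w)
    ch[!enc$mask] <- 0
    out[, , k] <- ch
  }
  out
}

#' Write region statistics as CSV rows
#'
#' Emits rows `{image, roi, n, mean, sd, cov, skewness}`.
#'
#' @param stats_list Named list of `region_stats` (names = ROI labels).
#' @param path Output CSV path.
#' @param image Image label recorded in each row.
#' @return The data frame written, invisibly.
#' @export
write_stats_csv <- function(stats_list, path, image = "ndvi") {
  stopifnot(is.list(stats_list), length(stats_list) >= 1L)
  d <- do.call(rbind, lapply(names(stats_list), function(nm) {
    s <- stats_list[[nm]]
    data.frame(image = image, roi = nm, n = s$n, mean = s$mean, sd = s$sd,
               cov = s$cov, skewness = s$skewness)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(d)
}
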