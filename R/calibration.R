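## Empirical-line calibration: DN -> reflectance via a six-material
## reference panel, with the camera's gamma curve fitted (or fixed).

.default_panel_materials <- function() {
  data.frame(
    name = c("White", "Sand", "Brown", "Indian Burch", "Forest Green",
             "Burgundy"),
    red_reflectance = c(92.69, 63.59, 16.29, 66.72, 4.90, 25.53),
    nir_reflectance = c(87.62, 60.85, 16.13, 62.69, 5.88, 39.40),
    stringsAsFactors = FALSE
  )
}

#' Reference calibration panel
#'
#' The packaged default is the six-material calibration board: diffuse
#' fabric squares with measured red (620--680 nm) and NIR (720--750 nm)
#' relative reflectances (White 92.69/87.62, Sand 63.59/60.85, Brown
#' 16.29/16.13, Indian Burch 66.72/62.69, Forest Green 4.90/5.88,
#' Burgundy 25.53/39.40).  ROIs locate each material patch in an image as
#' 0-based half-open rectangles `(row0, col0, height, width)`.
#'
#' @param materials Data frame with columns `name`, `red_reflectance`,
#'   `nir_reflectance` (percent); defaults to the packaged six materials.
#' @param rois Optional numeric matrix (one row per material) with columns
#'   `row0, col0, height, width`.
#' @return An object of class `reference_panel`.
#' @examples
#' reference_panel()$materials
#' @export
reference_panel <- function(materials = NULL, rois = NULL) {
  if (is.null(materials)) materials <- .default_panel_materials()
  stopifnot(is.data.frame(materials),
            all(c("name", "red_reflectance", "nir_reflectance") %in%
                  names(materials)))
  refl <- c(materials$red_reflectance, materials$nir_reflectance)
  if (any(!is.finite(refl)) || any(refl < 0 | refl > 100)) {
    stop("panel reflectances must lie in [0, 100] percent")
  }
  if (!is.null(rois)) {
    rois <- as.matrix(rois)
    if (nrow(rois) != nrow(materials) || ncol(rois) != 4L) {
      stop("rois must be one (row0, col0, height, width) row per material")
    }
    if (any(rois[, 3:4] < 1)) stop("ROI height and width must be >= 1")
    if (.rois_overlap(rois)) stop("panel ROIs must not overlap")
    colnames(rois) <- c("row0", "col0", "height", "width")
  }
  structure(list(materials = materials, rois = rois),
            class = "reference_panel")
}

.rois_overlap <- function(rois) {
  n <- nrow(rois)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- rois[i, ]; b <- rois[j, ]
    if (a[1] < b[1] + b[3] && b[1] < a[1] + a[3] &&
        a[2] < b[2] + b[4] && b[2] < a[2] + a[4]) return(TRUE)
  }
  FALSE
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d materials%s\n", nrow(x$materials),
              if (is.null(x$rois)) " (no ROIs)" else ""))
  print(x$materials)
  invisible(x)
}

#' Read / write a panel definition CSV
#'
#' CSV columns: `name`, `red_reflectance`, `nir_reflectance` (percent).
#' The packaged default panel ships as
#' `system.file("extdata", "reference_panel.csv", package = "ndvipipe")`.
#'
#' @param path CSV file path.
#' @param rois Optional ROI matrix passed to [reference_panel()].
#' @return A [reference_panel()].
#' @export
read_panel_csv <- function(path, rois = NULL) {
  reference_panel(utils::read.csv(path, stringsAsFactors = FALSE), rois)
}

#' @rdname read_panel_csv
#' @param panel A [reference_panel()].
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "reference_panel"))
  utils::write.csv(panel$materials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Mean DN of one patch: erode a 10% margin per side, optionally drop
## saturated pixels (DN >= 250).
.patch_mean <- function(dn, roi, exclude_saturated = TRUE,
                        saturation_dn = 250) {
  r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (r0 < 0 || c0 < 0 || r0 + h > nrow(dn) || c0 + w > ncol(dn)) {
    stop(sprintf("ROI (%d,%d,%d,%d) lies outside the %d x %d image",
                 r0, c0, h, w, nrow(dn), ncol(dn)))
  }
  mr <- floor(0.1 * h); mc <- floor(0.1 * w)
  rows <- (r0 + mr + 1):(r0 + h - mr)
  cols <- (c0 + mc + 1):(c0 + w - mc)
  px <- dn[rows, cols]
  n_total <- length(px)
  if (exclude_saturated) {
    keep <- px < saturation_dn
    if (sum(keep) < n_total / 2) {
      stop(sprintf(
        "saturated patch: %d of %d interior pixels have DN >= %d",
        n_total - sum(keep), n_total, saturation_dn))
    }
    px <- px[keep]
  }
  mean(px)
}

#' Mean digital number of each panel patch
#'
#' For each material ROI, averages the digital numbers of the patch
#' interior after eroding a 10% margin per side and excluding pixels with
#' DN >= 250.  A patch whose mean is >= 240 triggers a saturation warning
#' (exposure should be chosen so the brightest reference stays below DN
#' 240); a patch with more than half its interior saturated is an error.
#'
#' @param img A [digital_image()].
#' @param panel A [reference_panel()] with ROIs.
#' @param channel Channel label to read, e.g. `"red"`.
#' @return Numeric vector of mean DNs, in panel material order.
#' @export
extract_panel_means <- function(img, panel, channel = "red") {
  stopifnot(inherits(img, "digital_image"),
            inherits(panel, "reference_panel"))
  if (is.null(panel$rois)) stop("panel has no ROIs")
  dn <- image_channel(img, channel)
  means <- vapply(seq_len(nrow(panel$rois)), function(i) {
    .patch_mean(dn, panel$rois[i, ])
  }, numeric(1))
  names(means) <- panel$materials$name
  sat <- means >= 240
  if (any(sat)) {
    warning(sprintf("panel patch mean DN >= 240 (near saturation): %s",
                    paste(names(means)[sat], collapse = ", ")))
  }
  means
}

#' Fit the empirical-line DN-to-reflectance calibration
#'
#' Fits `R/100 = a * (DN/255)^gamma + b` by least squares.  In
#' six-reference mode `gamma` is free on \[1, 4\] (profiled: for each
#' candidate gamma the linear coefficients solve in closed form, leaving
#' a smooth 1-D search over the exponent).  In two-reference mode only the brightest and darkest
#' references are used, `gamma` is fixed (default 2.12766, the empirically
#' determined de-gamma power) and `a`, `b` solve the 2x2 system exactly.
#'
#' @param dn_means Mean digital numbers of the reference patches.
#' @param known_reflectances Known reflectances (percent), same order.
#' @param mode `"six-reference"` (default) or `"two-reference"`.
#' @param fixed_gamma Optional fixed gamma exponent.  Required meaning in
#'   two-reference mode (default 2.12766); if supplied in six-reference
#'   mode the exponent is not fitted.
#' @return An object of class `el_calibration` with components `a`, `b`,
#'   `gamma`, `mode`, `rmse` (percent, over the fitted points), `n_refs`,
#'   and the input data.  Methods: [print()], [coef()], [predict()],
#'   [residuals()].
#' @examples
#' panel <- reference_panel()$materials
#' dn <- 255 * (panel$red_reflectance / 100)^(1 / 2.12766)
#' fit <- fit_calibration(dn, panel$red_reflectance)
#' coef(fit)  # gamma recovered near 2.12766
#' @export
fit_calibration <- function(dn_means, known_reflectances,
                            mode = c("six-reference", "two-reference"),
                            fixed_gamma = NULL) {
  mode <- match.arg(mode)
  dn <- as.numeric(dn_means)
  refl <- as.numeric(known_reflectances)
  stopifnot(length(dn) == length(refl), all(is.finite(dn)),
            all(is.finite(refl)))
  if (!is.null(fixed_gamma)) {
    stopifnot(is.numeric(fixed_gamma), length(fixed_gamma) == 1L,
              fixed_gamma >= 1, fixed_gamma <= 4)
  }

  if (mode == "two-reference") {
    if (length(dn) > 2L) {            # keep brightest and darkest references
      sel <- c(which.max(dn), which.min(dn))
      dn <- dn[sel]; refl <- refl[sel]
    }
    if (length(dn) != 2L || dn[1] == dn[2]) {
      stop("two-reference mode needs exactly two distinct references")
    }
    gamma <- if (is.null(fixed_gamma)) 2.12766 else fixed_gamma
    x <- (dn / 255)^gamma
    a <- (refl[1] - refl[2]) / 100 / (x[1] - x[2])
    b <- refl[1] / 100 - a * x[1]
    fitted <- 100 * (a * x + b)
    gamma_fitted <- FALSE
  } else {
    if (length(unique(dn)) < 4L) {
      if (length(unique(dn)) == 1L) stop("singular fit: all DN values equal")
      stop("six-reference mode needs at least 4 distinct DN values")
    }
    sse_for <- function(g) {
      x <- (dn / 255)^g
      fit <- stats::lm.fit(cbind(1, x), refl / 100)
      sum(fit$residuals^2)
    }
    if (is.null(fixed_gamma)) {
      ## profiled 1-D search: for each gamma the linear coefficients have
      ## a closed form, so the exponent is found by golden-section search
      ## on [1, 4]
      opt <- stats::optimize(sse_for, c(1, 4), tol = 1e-9)
      if (!is.finite(opt$objective)) {
        stop("calibration fit did not converge: non-finite residual sum")
      }
      gamma <- opt$minimum
      ## optimize() never evaluates exactly at the bounds; snap when the
      ## boundary fits at least as well
      for (g_edge in c(1, 4)) {
        if (abs(gamma - g_edge) < 1e-4 && sse_for(g_edge) <= opt$objective) {
          gamma <- g_edge
        }
      }
      gamma_fitted <- TRUE
    } else {
      gamma <- fixed_gamma
      gamma_fitted <- FALSE
    }
    x <- (dn / 255)^gamma
    fit <- stats::lm.fit(cbind(1, x), refl / 100)
    b <- fit$coefficients[1]; a <- fit$coefficients[2]
    if (!all(is.finite(c(a, b)))) stop("singular fit: collinear DN values")
    fitted <- 100 * (a * x + b)
  }

  res <- refl - fitted
  structure(list(
    a = unname(a), b = unname(b), gamma = unname(gamma), mode = mode,
    rmse = sqrt(mean(res^2)), n_refs = length(dn),
    gamma_fitted = gamma_fitted, dn = dn, reflectance = refl,
    fitted = fitted, residuals = res
  ), class = "el_calibration")
}

#' @export
print.el_calibration <- function(x, ...) {
  cat(sprintf("Empirical-line calibration (%s, n = %d)\n", x$mode, x$n_refs))
  cat(sprintf("  R/100 = %.5f * (DN/255)^%.5f + %.5f\n", x$a, x$gamma, x$b))
  cat(sprintf("  gamma %s, rmse %.4f%%\n",
              if (x$gamma_fitted) "fitted" else "fixed", x$rmse))
  invisible(x)
}

#' @export
coef.el_calibration <- function(object, ...) {
  c(a = object$a, b = object$b, gamma = object$gamma)
}

#' @export
residuals.el_calibration <- function(object, ...) object$residuals

#' Predict reflectance from digital numbers
#'
#' @param object An `el_calibration` fit.
#' @param newdata Numeric DNs in \[0, 255\]; defaults to the fitted DNs.
#' @param clamp Clamp predictions onto \[0, 100\] (default `FALSE`).
#' @param ... Unused.
#' @return Reflectance percent.
#' @export
predict.el_calibration <- function(object, newdata = NULL, clamp = FALSE,
                                   ...) {
  dn <- if (is.null(newdata)) object$dn else as.numeric(newdata)
  r <- 100 * (object$a * (dn / 255)^object$gamma + object$b)
  if (clamp) r <- pmin(pmax(r, 0), 100)
  r
}

#' Convert a whole image to reflectance
#'
#' Applies a fitted calibration per pixel:
#' `R = 100 * (a * (DN/255)^gamma + b)`, clamped onto \[0, 100\] with
#' clamped pixels flagged.  The mapping is monotone in DN for `a > 0`.
#'
#' @param img A [digital_image()].
#' @param model An `el_calibration` fit.
#' @param channel Channel label to convert.
#' @param band A [band_definition()] to tag the output with.
#' @return A [reflectance_image()].
#' @export
apply_calibration <- function(img, model, channel = "red",
                              band = band_definition(channel, 620)) {
  stopifnot(inherits(img, "digital_image"),
            inherits(model, "el_calibration"))
  dn <- image_channel(img, channel)
  r <- 100 * (model$a * (dn / 255)^model$gamma + model$b)
  clamped <- r < 0 | r > 100
  r <- pmin(pmax(r, 0), 100)
  reflectance_image(r, band, matrix(TRUE, nrow(r), ncol(r)), clamped)
}

#' Select the exposure from a bracketed series
#'
#' From a series of exposures at strictly increasing shutter speeds,
#' returns the largest shutter speed at which the brightest panel patch
#' still has a mean DN below 240 (the saturation headroom needed to
#' calibrate over the full 0--100% reflectance range).
#'
#' @param exposure_series List of `list(shutter_speed = µs, image =
#'   digital_image)` entries, shutter speeds strictly increasing.
#' @param panel A [reference_panel()] with ROIs.
#' @param channel Channel label.
#' @return The selected shutter speed (µs), with attribute
#'   `"brightest_dn"` giving the brightest panel mean at that exposure.
#' @export
select_shutter_speed <- function(exposure_series, panel, channel = "red") {
  stopifnot(is.list(exposure_series), length(exposure_series) >= 2L)
  shutters <- vapply(exposure_series, function(e) e$shutter_speed, numeric(1))
  if (any(diff(shutters) <= 0)) {
    stop("shutter speeds must be strictly increasing")
  }
  if (is.null(panel$rois)) stop("panel has no ROIs")
  brightest <- vapply(exposure_series, function(e) {
    dn <- image_channel(e$image, channel)
    max(vapply(seq_len(nrow(panel$rois)), function(i) {
      .patch_mean(dn, panel$rois[i, ], exclude_saturated = FALSE)
    }, numeric(1)))
  }, numeric(1))
  ok <- brightest < 240
  if (!any(ok)) {
    stop("all exposures saturated: no shutter speed with brightest panel DN < 240")
  }
  i <- max(which(ok))
  structure(shutters[i], brightest_dn = brightest[i])
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model An `el_calibration` fit.
#' @param path JSON file path.
#' @return `read_calibration_json()` returns an `el_calibration`.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "el_calibration"))
  jsonlite::write_json(
    list(a = model$a, b = model$b, gamma = model$gamma, mode = model$mode,
         rmse = model$rmse, n_refs = model$n_refs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a = j$a, b = j$b, gamma = j$gamma, mode = j$mode,
                 rmse = j$rmse, n_refs = j$n_refs,
                 gamma_fitted = identical(j$mode, "six-reference"),
                 dn = numeric(0), reflectance = numeric(0),
                 fitted = numeric(0), residuals = numeric(0)),
            class = "el_calibration")
}
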