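## Ground-truthed synthetic scenes: chlorophyll-dependent leaf spectra, a
## six-material calibration board, a two-camera model with gamma,
## saturation, red leak, misalignment and noise, and a simulated
## spectrometer.  Everything is deterministic given the scene seed.

#' Leaf model parameters
#'
#' Inputs of the leaf radiative-transfer sweep the simulator emulates.
#' Only chlorophyll content drives the simplified reflectance model; the
#' remaining parameters are stored for provenance.
#'
#' @param cab Chlorophyll a+b content, µg cm^-2 (standard sweep 0--60).
#' @param structure_n Leaf structure parameter (dimensionless).
#' @param carotenoid Carotenoid content, µg cm^-2.
#' @param brown Brown pigment content (dimensionless).
#' @param ewt Equivalent water thickness, cm.
#' @param lma Leaf mass per unit area, g cm^-2.
#' @return An object of class `leaf_model_params`.
#' @export
leaf_model_params <- function(cab, structure_n = 1.2, carotenoid = 10,
                              brown = 1.0, ewt = 0.015, lma = 0.009) {
  vals <- c(cab, structure_n, carotenoid, brown, ewt, lma)
  stopifnot(all(is.finite(vals)), all(vals >= 0))
  structure(list(cab = cab, structure_n = structure_n,
                 carotenoid = carotenoid, brown = brown, ewt = ewt,
                 lma = lma),
            class = "leaf_model_params")
}

#' Simplified chlorophyll-dependent leaf reflectance
#'
#' A parametric stand-in for a full plate-model leaf simulation, built to
#' reproduce the properties the pipeline depends on: red reflectance
#' decreases with chlorophyll, with sensitivity peaking at the 680 nm
#' chlorophyll absorption maximum and fading with spectral distance from
#' it, while the NIR plateau is pigment-independent.
#'
#' For wavelengths <= 700 nm:
#' `R = 2 + 48 * exp(-k(lambda) * cab)` with
#' `k(lambda) = 0.08 * exp(-((lambda - 680) / 45)^2)`;
#' for wavelengths >= 750 nm, `R = 47` (flat, pigment-independent NIR
#' plateau); linear red-edge blend on (700, 750) nm, so NDVI is
#' insensitive to the NIR band choice only across 750--800 nm, as in
#' measured leaf spectra.  Deterministic, smooth, and strictly
#' decreasing in `cab` across the 600--700 nm red region.
#'
#' @param cab Chlorophyll a+b content, µg cm^-2 (>= 0).  Scalar or a
#'   vector matching `wavelength`.
#' @param wavelength Wavelength in nm, within \[400, 900\].
#' @return Reflectance percent.
#' @examples
#' leaf_reflectance(0, 620)   # 50
#' leaf_reflectance(60, 620)  # about 23.3
#' leaf_reflectance(30, 750)  # 47 (plateau)
#' @export
leaf_reflectance <- function(cab, wavelength) {
  stopifnot(is.numeric(cab), is.numeric(wavelength), all(cab >= 0))
  if (any(!is.finite(wavelength)) ||
      any(wavelength < 400 | wavelength > 900)) {
    stop("wavelength must lie in [400, 900] nm")
  }
  n <- max(length(cab), length(wavelength))
  cab <- rep_len(cab, n); wl <- rep_len(wavelength, n)
  red_part <- function(w, c) {
    k <- 0.08 * exp(-((w - 680) / 45)^2)
    2 + 48 * exp(-k * c)
  }
  r <- numeric(n)
  lo <- wl <= 700; hi <- wl >= 750; mid <- !lo & !hi
  r[lo] <- red_part(wl[lo], cab[lo])
  r[hi] <- 47
  if (any(mid)) {
    wgt <- (wl[mid] - 700) / 50
    r[mid] <- (1 - wgt) * red_part(700, cab[mid]) + wgt * 47
  }
  r
}

#' Scene regions
#'
#' Rectangular targets placed in a synthetic scene: either one of the
#' calibration-panel materials (by index into the panel material table) or
#' a leaf of given chlorophyll content.  Rectangles are 0-based half-open
#' `(row0, col0, height, width)`.
#'
#' @param index Panel material index (1-based row of the material table).
#' @param rect `c(row0, col0, height, width)`.
#' @return A region list for [scene_spec()].
#' @export
panel_region <- function(index, rect) {
  stopifnot(length(rect) == 4L, rect[3] >= 1, rect[4] >= 1)
  list(target = list(type = "panel", index = as.integer(index)),
       rect = as.numeric(rect))
}

#' @rdname panel_region
#' @param cab Leaf chlorophyll content, µg cm^-2.
#' @export
leaf_region <- function(cab, rect) {
  stopifnot(length(rect) == 4L, rect[3] >= 1, rect[4] >= 1, cab >= 0)
  list(target = list(type = "leaf", cab = as.numeric(cab)),
       rect = as.numeric(rect))
}

#' Synthetic scene specification
#'
#' Describes a scene for [render_scene()]: region layout, image size,
#' illumination, the rigid inter-camera misalignment, the red-leak
#' fraction of the NIR camera's filter, the camera gamma exponent, the
#' sensor noise level, and the random seed.  Defaults reflect the rig's
#' nominal operating conditions: 800 µmol m^-2 s^-1 irradiance, a small
#' fixed mount offset, a leak fraction of 0.10 (midpoint of the filter's
#' 5--15% red transmission), gamma 2.12766 and DN noise sd 1.5.
#'
#' @param regions List of [panel_region()] / [leaf_region()] entries.
#' @param width,height Image size in pixels.
#' @param illumination Irradiance, µmol m^-2 s^-1.
#' @param shift Inter-camera shift `c(dx, dy)` in pixels applied to the
#'   NIR frame.
#' @param leak_fraction Red-leak fraction `f` in \[0, 0.2\].
#' @param gamma Camera gamma exponent in \[1, 4\].
#' @param noise_sd Additive Gaussian DN noise sd (after gamma encoding,
#'   before rounding).
#' @param background Background reflectance `c(red, nir)` percent.
#' @param seed Integer random seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(regions, width, height, illumination = 800,
                       shift = c(2, -1), leak_fraction = 0.10,
                       gamma = 2.12766, noise_sd = 1.5,
                       background = c(10, 10), seed = 1L) {
  stopifnot(is.list(regions), length(regions) >= 1L,
            width >= 1, height >= 1,
            illumination > 0, length(shift) == 2L,
            leak_fraction >= 0, leak_fraction <= 0.2,
            gamma >= 1, gamma <= 4, noise_sd >= 0,
            length(background) == 2L, all(background >= 0),
            all(background <= 100))
  rects <- do.call(rbind, lapply(regions, `[[`, "rect"))
  if (any(rects[, 1] < 0 | rects[, 2] < 0 |
          rects[, 1] + rects[, 3] > height |
          rects[, 2] + rects[, 4] > width)) {
    stop("scene spec error: region outside image bounds")
  }
  if (.rois_overlap(rects)) stop("scene spec error: overlapping regions")
  structure(list(regions = regions, width = as.integer(width),
                 height = as.integer(height),
                 illumination = illumination, shift = as.numeric(shift),
                 leak_fraction = leak_fraction, gamma = gamma,
                 noise_sd = noise_sd, background = as.numeric(background),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Translate a plain matrix by (dx, dy) with bilinear resampling,
## filling out-of-frame pixels with a constant.
.translate_matrix <- function(v, dx, dy, fill) {
  h <- nrow(v); w <- ncol(v)
  ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
  iy0 <- floor(ys); fy <- ys[1] - iy0[1]
  ix0 <- floor(xs); fx <- xs[1] - ix0[1]
  iy1 <- if (fy > 1e-12) iy0 + 1L else iy0
  ix1 <- if (fx > 1e-12) ix0 + 1L else ix0
  vr <- which(iy0 >= 1 & iy1 <= h)
  vc <- which(ix0 >= 1 & ix1 <= w)
  out <- matrix(fill, h, w)
  if (length(vr) && length(vc)) {
    out[vr, vc] <-
      (1 - fy) * (1 - fx) * v[iy0[vr], ix0[vc], drop = FALSE] +
      (1 - fy) * fx       * v[iy0[vr], ix1[vc], drop = FALSE] +
      fy       * (1 - fx) * v[iy1[vr], ix0[vc], drop = FALSE] +
      fy       * fx       * v[iy1[vr], ix1[vc], drop = FALSE]
  }
  out
}

## Per-camera exposure gain: unity at nominal settings (red camera
## 400 µs, NIR camera 2500 µs) under 800 µmol m^-2 s^-1.  The NIR path
## additionally carries the filter's in-band throughput (~0.85: the
## blue plastic filter passes >80% of NIR), which keeps a properly
## exposed frame below saturation; calibration cancels it.
.camera_gain <- function(settings, role, illumination) {
  nominal <- if (role == "red-cam") 400 else 2500
  throughput <- if (role == "nir-cam") 0.85 else 1
  (illumination / 800) * (settings$shutter_speed / nominal) * throughput
}

## Gamma-encoding camera transform: reflectance % -> 8-bit DN.
.camera_dn <- function(refl, gain, gamma, noise) {
  lin <- pmax(gain * refl / 100, 0)
  dn <- round_half_away(255 * lin^(1 / gamma) + noise)
  matrix(as.integer(pmin(pmax(dn, 0), 255)), nrow(refl), ncol(refl))
}

#' Render a synthetic two-camera scene
#'
#' Builds per-pixel ground-truth red/NIR reflectance maps from the scene
#' layout (panel patches take the panel's known reflectances; leaves take
#' the leaf model evaluated at the camera band centres), then images them
#' with the two-camera model: the red camera sees the red reflectance;
#' the NIR camera sees `nir + f * red` (the filter leak), and its whole
#' frame is translated by the inter-camera shift.  Each camera applies a
#' shutter-proportional gain, the gamma power law
#' `DN = 255 * (gain * R/100)^(1/gamma)`, additive Gaussian DN noise, and
#' 8-bit rounding with saturation.  The same seed yields byte-identical
#' output.
#'
#' @param spec A [scene_spec()].
#' @param cameras List with elements `red` and `nir`, each a
#'   [camera_config()].  Defaults to the nominal settings (ISO 400;
#'   400 µs and 2500 µs).
#' @param panel A [reference_panel()] supplying panel-material
#'   reflectances.
#' @param red_band,nir_band Camera band centres used for leaf truth.
#' @return List with `red` and `nir` ([digital_image()]s) and `truth`
#'   (class `scene_truth`): pre-leak reflectance maps in the red-camera
#'   frame, the chlorophyll map, shift, leak fraction and seed.
#' @export
render_scene <- function(spec,
                         cameras = list(
                           red = camera_config(400, 400),
                           nir = camera_config(400, 2500)),
                         panel = reference_panel(),
                         red_band = band_definition("red", 620),
                         nir_band = band_definition("nir", 750)) {
  stopifnot(inherits(spec, "scene_spec"), inherits(panel, "reference_panel"))
  h <- spec$height; w <- spec$width
  red_map <- matrix(spec$background[1], h, w)
  nir_map <- matrix(spec$background[2], h, w)
  cab_map <- matrix(NA_real_, h, w)
  for (rg in spec$regions) {
    rc <- rg$rect
    rows <- (rc[1] + 1):(rc[1] + rc[3]); cols <- (rc[2] + 1):(rc[2] + rc[4])
    if (rg$target$type == "panel") {
      m <- panel$materials[rg$target$index, ]
      red_map[rows, cols] <- m$red_reflectance
      nir_map[rows, cols] <- m$nir_reflectance
    } else {
      red_map[rows, cols] <- leaf_reflectance(rg$target$cab,
                                              red_band$center_wavelength)
      nir_map[rows, cols] <- leaf_reflectance(rg$target$cab,
                                              nir_band$center_wavelength)
      cab_map[rows, cols] <- rg$target$cab
    }
  }

  f <- spec$leak_fraction
  nir_meas <- nir_map + f * red_map              # leak in the NIR frame
  nir_meas <- .translate_matrix(nir_meas, spec$shift[1], spec$shift[2],
                                fill = spec$background[2] +
                                       f * spec$background[1])

  g_red <- .camera_gain(cameras$red, "red-cam", spec$illumination)
  g_nir <- .camera_gain(cameras$nir, "nir-cam", spec$illumination)
  with_seed(spec$seed, {
    noise_red <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w) else 0
    noise_nir <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w) else 0
    red_dn <- .camera_dn(red_map, g_red, spec$gamma, noise_red)
    nir_dn <- .camera_dn(nir_meas, g_nir, spec$gamma, noise_nir)
  })

  truth <- structure(list(
    red_reflectance = red_map, nir_reflectance = nir_map,
    cab_map = cab_map, shift = spec$shift, leak_fraction = f,
    seed = spec$seed
  ), class = "scene_truth")

  list(
    red = digital_image(red_dn, "red", "red-cam", cameras$red),
    nir = digital_image(nir_dn, "red", "nir-cam", cameras$nir),
    truth = truth
  )
}

#' Standard calibration-board layout
#'
#' Places the six panel materials as two rows of three square patches and
#' returns both the scene regions and the matching panel ROI matrix.
#'
#' @param patch Patch side length in pixels.
#' @param gap Gap between patches in pixels.
#' @param row0,col0 Top-left corner of the board.
#' @return List with `regions` (for [scene_spec()]), `rois` (for
#'   [reference_panel()]), and the board `height`/`width` footprint.
#' @export
panel_board_layout <- function(patch = 24, gap = 6, row0 = 4, col0 = 4) {
  regions <- vector("list", 6L)
  rois <- matrix(0, 6L, 4L,
                 dimnames = list(NULL, c("row0", "col0", "height", "width")))
  for (i in 0:5) {
    r <- row0 + (i %/% 3) * (patch + gap)
    c <- col0 + (i %% 3) * (patch + gap)
    regions[[i + 1L]] <- panel_region(i + 1L, c(r, c, patch, patch))
    rois[i + 1L, ] <- c(r, c, patch, patch)
  }
  list(regions = regions, rois = rois,
       height = row0 + 2 * patch + gap,
       width = col0 + 3 * patch + 2 * gap)
}

#' Leaf-sweep scene
#'
#' Convenience constructor for the standard verification scene: the
#' six-material calibration board plus a grid of leaf patches spanning a
#' chlorophyll sweep.  This is the study condition used throughout the
#' verification tests: 24 leaves from 5 to 60 µg cm^-2 by default.
#'
#' @param cabs Chlorophyll contents of the leaf patches, µg cm^-2.
#' @param patch Leaf patch side length in pixels.
#' @param ... Passed to [scene_spec()] (e.g. `seed`, `noise_sd`, `shift`,
#'   `leak_fraction`, `illumination`).
#' @return List with `spec` (a [scene_spec()]), `panel` (a
#'   [reference_panel()] carrying the board ROIs), `leaf_rois` (matrix of
#'   leaf rectangles, one row per leaf) and `cabs`.
#' @export
make_leaf_scene <- function(cabs = seq(5, 60, length.out = 24), patch = 20,
                            ...) {
  board <- panel_board_layout()
  gap <- 5
  per_row <- 6L
  n <- length(cabs)
  nrows <- ceiling(n / per_row)
  leaf_row0 <- board$height + 10
  regions <- board$regions
  rois <- matrix(0, n, 4L,
                 dimnames = list(NULL, c("row0", "col0", "height", "width")))
  for (i in seq_len(n)) {
    r <- leaf_row0 + ((i - 1L) %/% per_row) * (patch + gap)
    c <- 4 + ((i - 1L) %% per_row) * (patch + gap)
    regions[[length(regions) + 1L]] <- leaf_region(cabs[i], c(r, c, patch, patch))
    rois[i, ] <- c(r, c, patch, patch)
  }
  height <- leaf_row0 + nrows * (patch + gap) + 6
  width <- max(board$width, 4 + per_row * (patch + gap)) + 4
  spec <- scene_spec(regions, width = width, height = height, ...)
  list(spec = spec,
       panel = reference_panel(rois = board$rois),
       leaf_rois = rois, cabs = cabs)
}

#' Simulated spectrometer
#'
#' Returns reflectance spectra on a 1 nm grid for a list of targets.  Leaf
#' targets use the simplified leaf model; a `"spectralon"` target returns
#' the flat 99% curve of a diffuse reflectance standard.  Output is
#' percent reflectance relative to the 99% standard (for simulated
#' targets the measured/standard ratio reduces to the model reflectance
#' itself).
#'
#' @param targets List of targets: `list(type = "leaf", cab = ...)`,
#'   `list(type = "spectralon")`, or a bare number (leaf chlorophyll).
#' @param grid Wavelength grid in nm within \[400, 900\].
#' @return Named list of [spectral_curve()]s.
#' @export
simulate_spectrometer <- function(targets, grid = 400:900) {
  stopifnot(all(grid >= 400), all(grid <= 900))
  out <- lapply(targets, function(t) {
    if (is.numeric(t)) t <- list(type = "leaf", cab = t)
    if (t$type == "spectralon") {
      spectral_curve(grid, rep(99, length(grid)))
    } else if (t$type == "leaf") {
      spectral_curve(grid, leaf_reflectance(t$cab, grid))
    } else {
      stop("unknown spectrometer target type: ", t$type)
    }
  })
  names(out) <- vapply(seq_along(targets), function(i) {
    t <- targets[[i]]
    if (is.numeric(t)) sprintf("leaf_cab%g", t)
    else if (t$type == "leaf") sprintf("leaf_cab%g", t$cab)
    else t$type
  }, character(1))
  out
}

#' Write simulated spectra as CSV
#'
#' Long format: columns `target`, `wavelength_nm`, `value`.
#'
#' @param spectra Named list of [spectral_curve()]s.
#' @param path Output CSV path.
#' @export
write_spectra_csv <- function(spectra, path) {
  d <- do.call(rbind, lapply(names(spectra), function(nm) {
    data.frame(target = nm, wavelength_nm = spectra[[nm]]$wavelength_nm,
               value = spectra[[nm]]$value)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' @rdname write_spectra_csv
#' @return `read_spectra_csv()` returns a named list of
#'   [spectral_curve()]s.
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$target), function(s) {
    s <- s[order(s$wavelength_nm), ]
    spectral_curve(s$wavelength_nm, s$value)
  })
  out[unique(d$target)]
}
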