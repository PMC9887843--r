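## Top-level pipeline: captured camera frames -> calibrated reflectance ->
## aligned, leak-corrected band pair -> encoded NDVI image + region stats.

#' Pipeline run configuration
#'
#' Collects every input of [run_pipeline()] and validates it before any
#' computation.  Images may be given as file paths or in-memory
#' [digital_image()]s; the panel must carry patch ROIs.
#'
#' @param red_image,nir_image [digital_image()]s or PNG paths.
#' @param panel A [reference_panel()] with ROIs, or a panel CSV path (then
#'   `panel_rois` must be supplied).
#' @param panel_rois Optional ROI matrix when `panel` is a CSV path.
#' @param analysis_rois Optional named list (or matrix with rownames) of
#'   analysis rectangles `c(row0, col0, height, width)` for region stats.
#' @param mode Calibration mode, `"six-reference"` or `"two-reference"`.
#' @param fixed_gamma Optional fixed gamma exponent (see
#'   [fit_calibration()]).
#' @param leak_fraction Red-leak fraction; ignored when
#'   `filter_transmission` is given.
#' @param filter_transmission Optional [spectral_curve()] (or CSV path) of
#'   the NIR camera's filter; the leak fraction is then estimated with
#'   [estimate_leak_fraction()].
#' @param shift Optional known inter-camera [rigid_shift()] (or
#'   `c(dx, dy)`); estimated from the images when `NULL`.
#' @param search_radius Alignment search radius in pixels.
#' @param spec An [encoding_spec()].
#' @param red_band,nir_band [band_definition()]s of the two cameras.
#' @param calibration_red,calibration_nir Optional pre-fitted
#'   `el_calibration` models (or JSON paths) reused instead of fitting on
#'   the in-scene panel.
#' @param out_dir Optional output directory; when given, the NDVI PNG,
#'   sidecar, mask, stats CSV, calibration JSONs and a JSON run summary
#'   are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(red_image, nir_image, panel, panel_rois = NULL,
                       analysis_rois = NULL,
                       mode = c("six-reference", "two-reference"),
                       fixed_gamma = NULL, leak_fraction = 0,
                       filter_transmission = NULL, shift = NULL,
                       search_radius = 10, spec = encoding_spec(),
                       red_band = band_definition("red", 620),
                       nir_band = band_definition("nir", 750),
                       calibration_red = NULL, calibration_nir = NULL,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(panel)) panel <- read_panel_csv(panel, panel_rois)
  stopifnot(inherits(panel, "reference_panel"))
  if (is.null(panel$rois)) {
    stop("config error: panel ROIs are required")
  }
  for (im in list(red_image, nir_image)) {
    if (!(inherits(im, "digital_image") ||
          (is.character(im) && file.exists(im)))) {
      stop("config error: images must be digital_image objects or existing PNG paths")
    }
  }
  if (is.character(filter_transmission)) {
    filter_transmission <- read_spectral_curve(filter_transmission)
  }
  if (!is.null(analysis_rois)) {
    if (is.matrix(analysis_rois)) {
      analysis_rois <- stats::setNames(
        lapply(seq_len(nrow(analysis_rois)),
               function(i) analysis_rois[i, ]),
        rownames(analysis_rois) %||%
          paste0("roi", seq_len(nrow(analysis_rois))))
    }
    ok <- vapply(analysis_rois, function(r)
      is.numeric(r) && length(r) == 4L && all(r[3:4] >= 1), logical(1))
    if (!all(ok)) stop("config error: invalid analysis ROI")
  }
  load_cal <- function(x) {
    if (is.character(x)) read_calibration_json(x) else x
  }
  structure(list(
    red_image = red_image, nir_image = nir_image, panel = panel,
    analysis_rois = analysis_rois, mode = mode, fixed_gamma = fixed_gamma,
    leak_fraction = leak_fraction,
    filter_transmission = filter_transmission, shift = shift,
    search_radius = search_radius, spec = spec,
    red_band = red_band, nir_band = nir_band,
    calibration_red = load_cal(calibration_red),
    calibration_nir = load_cal(calibration_nir),
    out_dir = out_dir
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML or JSON
#'
#' The file holds the fields of [run_config()] with images and the panel
#' given as paths; `panel_rois` and `analysis_rois` are given as lists of
#' `[row0, col0, height, width]` rectangles (analysis ROIs named).
#' Relative paths are resolved against the config file's directory.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(path)
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  as_roi_matrix <- function(x) {
    if (is.null(x)) return(NULL)
    do.call(rbind, lapply(x, as.numeric))
  }
  arois <- cfg$analysis_rois
  if (!is.null(arois)) arois <- lapply(arois, as.numeric)
  run_config(
    red_image = rel(cfg$red_image), nir_image = rel(cfg$nir_image),
    panel = rel(cfg$panel), panel_rois = as_roi_matrix(cfg$panel_rois),
    analysis_rois = arois,
    mode = cfg$mode %||% "six-reference",
    fixed_gamma = cfg$fixed_gamma,
    leak_fraction = cfg$leak_fraction %||% 0,
    filter_transmission = rel(cfg$filter_transmission),
    shift = if (!is.null(cfg$shift)) as.numeric(cfg$shift),
    search_radius = cfg$search_radius %||% 10,
    out_dir = cfg$out_dir
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full NDVI pipeline
#'
#' Executes, in order: load images; determine the leak fraction; extract
#' panel means for both cameras; fit one calibration per camera (the NIR
#' camera is calibrated against leak-adjusted references `nir + f * red`,
#' so its calibrated image is total in-band signal and the leak
#' correction then removes exactly the red share); convert both frames to
#' reflectance; estimate the inter-camera shift and resample the NIR
#' frame onto the red frame; subtract the red leak; compute and encode
#' the NDVI image; compute region statistics.  Every stage logs a summary
#' line; a failing stage aborts with an error naming the stage.
#'
#' @param config A [run_config()] (or arguments for one).
#' @return List with `ndvi` ([encoded_image()]), `stats` (named list of
#'   `region_stats`), `calibration` (red/nir `el_calibration`s), `shift`,
#'   `leak` ([leak_model()]), `red`/`nir` (aligned, corrected
#'   [reflectance_image()]s) and `paths` (written files, if `out_dir`
#'   was set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) message(sprintf(...))

  imgs <- .stage("load-images", {
    red <- if (is.character(config$red_image)) {
      read_image(config$red_image, "red-cam")
    } else config$red_image
    nir <- if (is.character(config$nir_image)) {
      read_image(config$nir_image, "nir-cam")
    } else config$nir_image
    if (red$camera_role != "red-cam" || nir$camera_role != "nir-cam") {
      stop("camera_role mismatch: expected red-cam + nir-cam pair")
    }
    list(red = red, nir = nir)
  })
  log_msg("load-images: red %dx%d, nir %dx%d",
          nrow(imgs$red$pixels), ncol(imgs$red$pixels),
          nrow(imgs$nir$pixels), ncol(imgs$nir$pixels))

  leak <- .stage("leak-model", {
    if (!is.null(config$filter_transmission)) {
      estimate_leak_fraction(config$filter_transmission,
                             config$red_band, config$nir_band)
    } else {
      leak_model(config$leak_fraction)
    }
  })
  log_msg("leak-model: fraction %.4f", leak$fraction)

  panel <- config$panel
  cals <- .stage("calibration", {
    refl_red <- panel$materials$red_reflectance
    ## the NIR channel of the panel carries the red leak too
    refl_nir <- panel$materials$nir_reflectance +
      leak$fraction * panel$materials$red_reflectance
    cal_red <- config$calibration_red %||% {
      dn <- extract_panel_means(imgs$red, panel, "red")
      fit_calibration(dn, refl_red, config$mode, config$fixed_gamma)
    }
    cal_nir <- config$calibration_nir %||% {
      dn <- extract_panel_means(imgs$nir, panel, "red")
      fit_calibration(dn, refl_nir, config$mode, config$fixed_gamma)
    }
    list(red = cal_red, nir = cal_nir)
  })
  log_msg("calibration: red gamma %.4f rmse %.3f%%; nir gamma %.4f rmse %.3f%%",
          cals$red$gamma, cals$red$rmse, cals$nir$gamma, cals$nir$rmse)

  refl <- .stage("apply-calibration", list(
    red = apply_calibration(imgs$red, cals$red, "red", config$red_band),
    nir = apply_calibration(imgs$nir, cals$nir, "red", config$nir_band)
  ))

  shift <- .stage("alignment", {
    s <- config$shift
    if (is.null(s)) {
      s <- estimate_shift(refl$red, refl$nir, config$search_radius)
    } else if (is.numeric(s)) {
      s <- rigid_shift(s[1], s[2])
    }
    s
  })
  log_msg("alignment: shift dx %+0.2f, dy %+0.2f (score %.3f)",
          shift$dx, shift$dy, shift$score)
  nir_aligned <- .stage("alignment",
                        apply_shift(refl$nir, invert_shift(shift)))

  nir_corr <- .stage("leak-correction",
                     correct_nir_leak(nir_aligned, refl$red, leak))
  log_msg("leak-correction: subtracted %.4f x red", leak$fraction)

  ndvi <- .stage("ndvi", build_ndvi_image(refl$red, nir_corr, config$spec))
  log_msg("ndvi: %d/%d valid pixels, code range [%d, %d]",
          sum(ndvi$mask), length(ndvi$mask), min(ndvi$codes),
          max(ndvi$codes))

  stats <- NULL
  if (!is.null(config$analysis_rois)) {
    stats <- .stage("region-stats", {
      vals <- decode_ndvi(ndvi)
      lapply(config$analysis_rois, function(r) region_stats(vals, r))
    })
  }

  paths <- NULL
  if (!is.null(config$out_dir)) {
    paths <- .stage("write-outputs", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      p_ndvi <- file.path(config$out_dir, "ndvi.png")
      write_encoded_png(ndvi, p_ndvi)
      p_cal_r <- file.path(config$out_dir, "calibration_red.json")
      p_cal_n <- file.path(config$out_dir, "calibration_nir.json")
      write_calibration_json(cals$red, p_cal_r)
      write_calibration_json(cals$nir, p_cal_n)
      p_stats <- NULL
      if (!is.null(stats)) {
        p_stats <- file.path(config$out_dir, "stats.csv")
        write_stats_csv(stats, p_stats)
      }
      p_sum <- file.path(config$out_dir, "run_summary.json")
      jsonlite::write_json(list(
        leak_fraction = leak$fraction,
        shift = list(dx = shift$dx, dy = shift$dy, score = shift$score),
        calibration = list(
          red = list(a = cals$red$a, b = cals$red$b,
                     gamma = cals$red$gamma, rmse = cals$red$rmse),
          nir = list(a = cals$nir$a, b = cals$nir$b,
                     gamma = cals$nir$gamma, rmse = cals$nir$rmse)),
        n_valid = sum(ndvi$mask)
      ), p_sum, auto_unbox = TRUE, digits = NA)
      c(ndvi = p_ndvi, calibration_red = p_cal_r, calibration_nir = p_cal_n,
        stats = p_stats, summary = p_sum)
    })
    log_msg("write-outputs: %d file(s) in %s", length(paths),
            config$out_dir)
  }

  list(ndvi = ndvi, stats = stats, calibration = cals, shift = shift,
       leak = leak, red = refl$red, nir = nir_corr, paths = paths)
}
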