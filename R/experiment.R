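## The standard verification experiment: image a chlorophyll sweep of
## synthetic leaves with the two-camera model, run the full pipeline, and
## pair the per-leaf camera NDVI with simulated spectrometer spectra.

#' Simulated leaf-sweep verification dataset
#'
#' Renders the standard leaf-sweep scene (calibration board plus leaf
#' patches across a chlorophyll range), runs the full pipeline
#' (six-reference calibration on the in-scene panel, alignment,
#' red-leak correction, NDVI), extracts per-leaf camera NDVI from eroded
#' leaf ROIs, and simulates matching spectrometer spectra.  This is the
#' input expected by [wavelength_sweep()].
#'
#' @param cabs Leaf chlorophyll contents, µg cm^-2.
#' @param seed Scene random seed.
#' @param noise_sd Camera DN noise sd.
#' @param leak_fraction Red-leak fraction of the scene and pipeline.
#' @param shift Inter-camera shift `c(dx, dy)`.
#' @param use_true_shift Align with the scene's true shift instead of
#'   estimating it (default `FALSE`).
#' @param illumination Scene irradiance, µmol m^-2 s^-1.
#' @param roi_margin Pixels eroded from each leaf ROI side before stats.
#' @return List with `camera_ndvi` (per-leaf means), `spectra` (list of
#'   [spectral_curve()]s), `truth_ndvi` (from the scene's reflectance
#'   truth), `cabs`, and `pipeline` (the [run_pipeline()] result).
#' @export
leaf_sweep_dataset <- function(cabs = seq(5, 60, length.out = 24),
                               seed = 1L, noise_sd = 1.5,
                               leak_fraction = 0.10, shift = c(2, -1),
                               use_true_shift = FALSE,
                               illumination = 800, roi_margin = 3) {
  scene <- make_leaf_scene(cabs, seed = seed, noise_sd = noise_sd,
                           leak_fraction = leak_fraction, shift = shift,
                           illumination = illumination)
  rendered <- render_scene(scene$spec)
  rois <- lapply(seq_len(nrow(scene$leaf_rois)), function(i) {
    scene$leaf_rois[i, ] + c(roi_margin, roi_margin,
                             -2 * roi_margin, -2 * roi_margin)
  })
  names(rois) <- sprintf("leaf_cab%g", cabs)
  cfg <- run_config(
    red_image = rendered$red, nir_image = rendered$nir,
    panel = scene$panel, analysis_rois = rois,
    leak_fraction = leak_fraction,
    shift = if (use_true_shift) shift else NULL,
    search_radius = 10)
  res <- suppressWarnings(run_pipeline(cfg))
  camera_ndvi <- vapply(res$stats, function(s) s$mean, numeric(1))
  truth_ndvi <- ndvi_value(leaf_reflectance(cabs, 750),
                           leaf_reflectance(cabs, 620))
  list(camera_ndvi = camera_ndvi,
       spectra = simulate_spectrometer(as.list(cabs)),
       truth_ndvi = truth_ndvi, cabs = cabs, pipeline = res)
}
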