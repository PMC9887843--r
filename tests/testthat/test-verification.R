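test_that("sweep self-consistency: camera NDVI from the same spectra", {
  cabs <- seq(10, 60, 10)
  spectra <- simulate_spectrometer(as.list(cabs))
  cam <- ndvi_value(leaf_reflectance(cabs, 750), leaf_reflectance(cabs, 620))
  sw <- wavelength_sweep(cam, spectra, "red")
  expect_equal(sw$best_wavelength, 620)
  expect_equal(min(sw$mean_abs_pct_diff), 0, tolerance = 1e-9)
  expect_true(all(diff(sw$wavelengths) > 0))
  ## the reported best attains the minimum
  expect_equal(sw$mean_abs_pct_diff[sw$wavelengths == sw$best_wavelength],
               min(sw$mean_abs_pct_diff))
})

test_that("NIR sweep is flat on the plateau and tie-breaks to 750", {
  cabs <- seq(10, 60, 10)
  spectra <- simulate_spectrometer(as.list(cabs))
  cam <- ndvi_value(leaf_reflectance(cabs, 750), leaf_reflectance(cabs, 620))
  sw <- wavelength_sweep(cam, spectra, "nir")
  expect_equal(sw$best_wavelength, 750)
  plateau <- sw$mean_abs_pct_diff[sw$wavelengths >= 750]
  expect_equal(max(plateau) - min(plateau), 0, tolerance = 1e-9)
})

test_that("refining the sweep step never raises the minimum", {
  cabs <- seq(5, 60, 5)
  spectra <- simulate_spectrometer(as.list(cabs))
  cam <- ndvi_value(leaf_reflectance(cabs, 750),
                    leaf_reflectance(cabs, 620)) + 0.01
  coarse <- wavelength_sweep(cam, spectra, "red", step = 10)
  fine <- wavelength_sweep(cam, spectra, "red", step = 1)
  expect_lte(min(fine$mean_abs_pct_diff), min(coarse$mean_abs_pct_diff))
})

test_that("sweep excludes zero-NDVI samples with a warning", {
  spectra <- simulate_spectrometer(list(30))
  ## a flat 47% spectrum gives NDVI exactly 0 against the 47% plateau
  flat <- spectral_curve(400:900, rep(47, 501))
  w <- capture_warnings(
    sw <- wavelength_sweep(c(0.2, 0.4), list(flat, spectra$leaf_cab30),
                           "red"))
  expect_gt(length(w), 0)
  expect_true(all(grepl("excluded", w)))
  expect_true(all(is.finite(sw$mean_abs_pct_diff)))
  expect_error(wavelength_sweep(0.2, list(flat), "red"), "degenerate")
})

test_that("end-to-end simulated sweep recovers the camera band centres", {
  ds <- leaf_sweep_dataset(seed = 11)
  expect_gte(length(ds$camera_ndvi), 20)
  expect_lt(max(abs(ds$camera_ndvi - ds$truth_ndvi)), 0.02)
  sw_red <- wavelength_sweep(ds$camera_ndvi, ds$spectra, "red")
  expect_equal(sw_red$best_wavelength, 620)
  sw_nir <- wavelength_sweep(ds$camera_ndvi, ds$spectra, "nir")
  expect_gte(sw_nir$best_wavelength, 750)
  expect_lte(sw_nir$best_wavelength, 800)
})

test_that("sweep minimum is invariant to illumination rescaling", {
  ds_hi <- leaf_sweep_dataset(seed = 21, illumination = 800)
  ds_lo <- leaf_sweep_dataset(seed = 21, illumination = 560)
  b_hi <- wavelength_sweep(ds_hi$camera_ndvi, ds_hi$spectra, "red")
  b_lo <- wavelength_sweep(ds_lo$camera_ndvi, ds_lo$spectra, "red")
  expect_equal(b_hi$best_wavelength, b_lo$best_wavelength)
})

test_that("compare_to_reference recovers exact and affine relationships", {
  x <- c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85)
  same <- compare_to_reference(x, x)
  expect_equal(same$r2, 1); expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  expect_equal(same$sd_diff, 0)
  aff <- compare_to_reference(0.86 * x + 0.03, x)
  expect_equal(aff$slope, 0.86, tolerance = 1e-12)
  expect_equal(aff$intercept, 0.03, tolerance = 1e-12)
  ## a constant offset leaves the difference sd at zero
  off <- compare_to_reference(x + 0.1, x)
  expect_equal(off$sd_diff, 0, tolerance = 1e-12)
  ## random affine recovery
  set.seed(31)
  for (i in 1:10) {
    a <- runif(1, -2, 2); b <- runif(1, -1, 1)
    if (abs(a) < 0.05) a <- 0.5
    r <- compare_to_reference(a * x + b, x)
    expect_equal(r$slope, a, tolerance = 1e-9)
    expect_equal(r$intercept, b, tolerance = 1e-9)
  }
  expect_error(compare_to_reference(x, rep(1, 6)), "zero variance")
  expect_error(compare_to_reference(1:2, 1:2), "length")
})

test_that("sweep results serialize to CSV", {
  cabs <- seq(10, 60, 10)
  spectra <- simulate_spectrometer(as.list(cabs))
  cam <- ndvi_value(leaf_reflectance(cabs, 750), leaf_reflectance(cabs, 620))
  sw <- wavelength_sweep(cam, spectra, "red")
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  back <- read.csv(f)
  expect_equal(back$wavelength_nm, sw$wavelengths)
  expect_equal(back$mean_abs_pct_diff, sw$mean_abs_pct_diff, tolerance = 1e-9)
})
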