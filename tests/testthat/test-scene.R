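test_that("leaf reflectance follows the chlorophyll absorption model", {
  expect_equal(leaf_reflectance(0, 620), 50)                 # exp(0) baseline
  expect_equal(leaf_reflectance(60, 620), 23.3268, tolerance = 1e-3)
  ## NIR plateau is chlorophyll independent
  expect_identical(leaf_reflectance(0, 750), leaf_reflectance(60, 750))
  expect_equal(leaf_reflectance(30, 750), 47)
  expect_equal(leaf_reflectance(30, 800), 47)
  ## sensitivity peaks at the 680 nm absorption maximum
  expect_lt(leaf_reflectance(30, 680), leaf_reflectance(30, 620))
  ## strictly decreasing in cab across the red region
  for (wl in c(600, 640, 680, 700)) {
    r <- leaf_reflectance(seq(0, 60, 5), wl)
    expect_true(all(diff(r) < 0))
  }
  expect_error(leaf_reflectance(10, 300), "wavelength")
  expect_error(leaf_reflectance(-1, 620), "cab")
})

test_that("leaf_model_params stores the provenance inputs", {
  p <- leaf_model_params(30)
  expect_equal(p$structure_n, 1.2)
  expect_equal(p$carotenoid, 10)
  expect_equal(p$ewt, 0.015)
  expect_error(leaf_model_params(-5), "vals")
})

test_that("scene rendering is deterministic and honours the camera model", {
  board <- panel_board_layout()
  sp <- scene_spec(board$regions, width = board$width + 4,
                   height = board$height + 4, noise_sd = 0,
                   shift = c(0, 0), leak_fraction = 0)
  sc <- render_scene(sp)
  ## White patch at unit gain, gamma 2.12766: DN 246
  expect_equal(sc$red$pixels[10, 10, 1], 246L)
  ## saturation clamps at 255 (double the illumination)
  sp_hot <- scene_spec(board$regions, width = board$width + 4,
                       height = board$height + 4, noise_sd = 0,
                       shift = c(0, 0), leak_fraction = 0,
                       illumination = 1600)
  expect_equal(render_scene(sp_hot)$red$pixels[10, 10, 1], 255L)
  ## same seed -> byte identical; different seed -> different noise
  spn <- scene_spec(board$regions, width = board$width + 4,
                    height = board$height + 4, seed = 5)
  a <- render_scene(spn); b <- render_scene(spn)
  expect_identical(a$red$pixels, b$red$pixels)
  expect_identical(a$nir$pixels, b$nir$pixels)
  spn2 <- scene_spec(board$regions, width = board$width + 4,
                     height = board$height + 4, seed = 6)
  expect_false(identical(render_scene(spn2)$red$pixels, a$red$pixels))
})

test_that("scene specs reject bad layouts", {
  r1 <- panel_region(1, c(0, 0, 10, 10))
  r2 <- panel_region(2, c(5, 5, 10, 10))
  expect_error(scene_spec(list(r1, r2), 40, 40), "overlapping")
  expect_error(scene_spec(list(panel_region(1, c(0, 0, 50, 10))), 40, 40),
               "outside image bounds")
})

test_that("scene truth matches the layout and the leak enters the NIR frame", {
  regions <- list(panel_region(6, c(0, 0, 10, 10)),
                  leaf_region(30, c(0, 14, 10, 10)))
  sp <- scene_spec(regions, width = 28, height = 14, noise_sd = 0,
                   shift = c(0, 0), leak_fraction = 0.1)
  sc <- render_scene(sp)
  expect_equal(sc$truth$red_reflectance[5, 5], 25.53)   # Burgundy red
  expect_equal(sc$truth$nir_reflectance[5, 5], 39.40)
  expect_equal(sc$truth$red_reflectance[5, 20], leaf_reflectance(30, 620))
  expect_equal(sc$truth$cab_map[5, 20], 30)
  expect_true(is.na(sc$truth$cab_map[5, 5]))
  ## NIR DN reflects nir + f*red through the camera transform (gain 0.85)
  sig <- (39.40 + 0.1 * 25.53) / 100 * 0.85
  expect_equal(sc$nir$pixels[5, 5, 1],
               as.integer(round(255 * sig^(1 / 2.12766))))
})

test_that("simulated spectrometer returns leaf curves and the 99% standard", {
  sp <- simulate_spectrometer(list(list(type = "spectralon"), 30))
  expect_equal(unique(sp$spectralon$value), 99)
  leaf <- sp$leaf_cab30
  at <- function(wl) leaf$value[leaf$wavelength_nm == wl]
  expect_lt(at(680), at(620))
  expect_equal(ndvi_value(at(750), at(620)),
               ndvi_value(leaf_reflectance(30, 750), leaf_reflectance(30, 620)))
})

test_that("spectral NDVI increases strictly with chlorophyll content", {
  cabs <- seq(0, 60, 5)       # the standard 13-leaf sweep
  nd <- ndvi_value(leaf_reflectance(cabs, 750), leaf_reflectance(cabs, 620))
  expect_true(all(diff(nd) > 0))
})

test_that("narrowband red at 668 nm yields higher NDVI than 620 nm", {
  for (cab in seq(20, 60, 10)) {
    nd_pi <- ndvi_value(leaf_reflectance(cab, 750), leaf_reflectance(cab, 620))
    nd_ms <- ndvi_value(leaf_reflectance(cab, 840), leaf_reflectance(cab, 668))
    expect_gt(nd_ms, nd_pi)
  }
})

test_that("spectra CSV round trip preserves curves", {
  sp <- simulate_spectrometer(list(10, 40))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(sp, f)
  back <- read_spectra_csv(f)
  expect_equal(names(back), names(sp))
  expect_equal(back$leaf_cab40$value, sp$leaf_cab40$value)
})
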