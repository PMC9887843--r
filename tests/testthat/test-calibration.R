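test_that("packaged panel carries the six reference materials", {
  p <- reference_panel()
  expect_equal(nrow(p$materials), 6)
  expect_equal(p$materials$name,
               c("White", "Sand", "Brown", "Indian Burch", "Forest Green",
                 "Burgundy"))
  csv <- read_panel_csv(system.file("extdata", "reference_panel.csv",
                                    package = "ndvipipe"))
  expect_equal(csv$materials$red_reflectance, p$materials$red_reflectance)
  expect_equal(csv$materials$nir_reflectance, p$materials$nir_reflectance)
  expect_error(reference_panel(rois = matrix(c(0, 0, 5, 5, 2, 2, 5, 5),
                                             2, 4, byrow = TRUE)),
               "one")  # wrong roi count
})

test_that("extract_panel_means recovers constant patch DNs and warns near saturation", {
  rois <- six_rois()
  dns <- c(246, 200, 120, 205, 62, 150)
  img <- patch_image(dns, rois, 60, 30)
  panel <- reference_panel(rois = rois)
  expect_warning(m <- extract_panel_means(img, panel, "red"),
                 "near saturation.*White")
  expect_equal(unname(m), dns)
  expect_length(m, 6)
})

test_that("extract_panel_means rejects out-of-bounds and saturated patches", {
  rois <- six_rois()
  panel <- reference_panel(rois = rois)
  small <- digital_image(matrix(100L, 20, 20), "red", "red-cam")
  expect_error(extract_panel_means(small, panel, "red"), "outside")
  sat <- patch_image(rep(255, 6), rois, 60, 30)
  expect_error(suppressWarnings(extract_panel_means(sat, panel, "red")),
               "saturated patch")
})

test_that("six-reference fit recovers the camera gamma from clean data", {
  refl <- reference_panel()$materials$red_reflectance
  dn <- 255 * (refl / 100)^(1 / 2.12766)
  fit <- fit_calibration(dn, refl)
  expect_equal(fit$gamma, 2.12766, tolerance = 1e-3)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$b, 0, tolerance = 1e-4)
  expect_lt(fit$rmse, 1e-3)
  ## linear data drives the exponent to the lower bound
  lin <- fit_calibration(255 * refl / 100, refl)
  expect_lte(lin$gamma, 1 + 1e-3)
})

test_that("two-reference mode solves the anchor system exactly", {
  fit <- fit_calibration(c(246, 62), c(92.69, 4.90), mode = "two-reference")
  expect_equal(fit$gamma, 2.12766)
  expect_equal(predict(fit, c(246, 62)), c(92.69, 4.90), tolerance = 1e-10)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  ## six values in: picks brightest and darkest
  refl <- reference_panel()$materials$red_reflectance
  dn <- c(246, 206, 109, 211, 62, 134)
  fit6 <- fit_calibration(dn, refl, mode = "two-reference")
  expect_equal(fit6$n_refs, 2)
  expect_equal(predict(fit6, c(246, 62)), c(92.69, 4.90), tolerance = 1e-10)
})

test_that("degenerate reference sets are rejected", {
  expect_error(fit_calibration(rep(100, 6), reference_panel()$materials$red_reflectance),
               "singular")
  expect_error(fit_calibration(c(10, 10, 20, 20, 30, 30), 1:6 * 10),
               "4 distinct")
})

test_that("parameter recovery: 100 random gamma curves refit within tolerance", {
  set.seed(101)
  dn_grid <- c(25, 60, 110, 150, 200, 246)
  worst_gamma <- 0
  worst_pred <- 0
  for (i in 1:100) {
    a <- runif(1, 0.8, 1.2); b <- runif(1, -0.05, 0.05)
    g <- runif(1, 1.2, 3.5)
    refl <- 100 * (a * (dn_grid / 255)^g + b)
    fit <- fit_calibration(dn_grid, refl)
    worst_gamma <- max(worst_gamma, abs(fit$gamma - g))
    worst_pred <- max(worst_pred, max(abs(predict(fit, dn_grid) - refl)))
  }
  expect_lt(worst_gamma, 1e-3)
  expect_lt(worst_pred, 0.1)
})

test_that("integer DN quantization perturbs the recovered gamma by < 0.05", {
  set.seed(202)
  dn_grid <- c(25, 60, 110, 150, 200, 246)
  for (i in 1:20) {
    g <- runif(1, 1.2, 3.5)
    refl <- 100 * (dn_grid / 255)^g
    dn_q <- round(255 * (refl / 100)^(1 / g))
    fit <- fit_calibration(dn_q, refl)
    expect_lt(abs(fit$gamma - g), 0.05)
  }
})

test_that("six references never fit worse than two on the same panel", {
  set.seed(303)
  refl <- reference_panel()$materials$red_reflectance
  better <- 0L
  n_trials <- 40L
  for (i in seq_len(n_trials)) {
    g <- runif(1, 1.2, 3.5)
    dn <- 255 * (refl / 100)^(1 / g) + rnorm(6, 0, 2)
    dn <- pmin(pmax(dn, 1), 254)
    f6 <- fit_calibration(dn, refl)
    f2 <- fit_calibration(dn, refl, mode = "two-reference")
    rmse6 <- sqrt(mean((predict(f6, dn) - refl)^2))
    rmse2 <- sqrt(mean((predict(f2, dn) - refl)^2))
    if (rmse6 <= rmse2 + 1e-9) better <- better + 1L
  }
  expect_gte(better / n_trials, 0.95)
})

test_that("apply_calibration converts whole frames monotonically with clamping", {
  refl <- reference_panel()$materials$red_reflectance
  dn <- 255 * (refl / 100)^(1 / 2.12766)
  fit <- fit_calibration(dn, refl)
  img <- digital_image(matrix(0:255, 16, 16), "red", "red-cam")
  out <- apply_calibration(img, fit, "red", red_band)
  expect_true(all(diff(as.vector(out$values)) >= 0))  # monotone in DN
  expect_true(all(out$values >= 0 & out$values <= 100))
  ## DN 0 with b = 0 -> 0%
  fit0 <- fit_calibration(dn, refl)
  fit0$b <- 0
  z <- apply_calibration(digital_image(matrix(0L, 2, 2), "red", "red-cam"),
                         fit0, "red", red_band)
  expect_equal(z$values, matrix(0, 2, 2))
})

test_that("calibrating a noiseless synthetic board reproduces the panel values", {
  board <- panel_board_layout()
  sp <- scene_spec(board$regions, width = board$width + 4,
                   height = board$height + 4, noise_sd = 0,
                   shift = c(0, 0), leak_fraction = 0)
  sc <- render_scene(sp)
  panel <- reference_panel(rois = board$rois)
  dn <- suppressWarnings(extract_panel_means(sc$red, panel, "red"))
  fit <- fit_calibration(dn, panel$materials$red_reflectance)
  out <- apply_calibration(sc$red, fit, "red", red_band)
  got <- vapply(seq_len(6), function(i) {
    r <- board$rois[i, ]
    mean(out$values[(r[1] + 3):(r[1] + r[3] - 2),
                    (r[2] + 3):(r[2] + r[4] - 2)])
  }, numeric(1))
  expect_equal(got, panel$materials$red_reflectance, tolerance = 0.5 / 50)
})

test_that("shutter selection keeps the brightest reference below DN 240", {
  panel <- single_patch_panel()
  mk <- function(dn) digital_image(matrix(as.integer(dn), 12, 12),
                                   "red", "red-cam")
  series <- list(
    list(shutter_speed = 400, image = mk(62)),
    list(shutter_speed = 800, image = mk(118)),
    list(shutter_speed = 1600, image = mk(210)),
    list(shutter_speed = 2500, image = mk(239)),
    list(shutter_speed = 5000, image = mk(255)))
  sel <- select_shutter_speed(series, panel, "red")
  expect_equal(as.numeric(sel), 2500)
  expect_lt(attr(sel, "brightest_dn"), 240)
  ## single qualifying exposure
  one <- select_shutter_speed(series[4:5], panel, "red")
  expect_equal(as.numeric(one), 2500)
  ## all saturated
  bad <- list(list(shutter_speed = 400, image = mk(240)),
              list(shutter_speed = 800, image = mk(250)))
  expect_error(select_shutter_speed(bad, panel, "red"), "all exposures saturated")
  ## non-increasing shutters
  expect_error(select_shutter_speed(rev(series[1:2]), panel, "red"),
               "strictly increasing")
})

test_that("calibration JSON round-trips the fitted parameters", {
  refl <- reference_panel()$materials$red_reflectance
  dn <- 255 * (refl / 100)^(1 / 2.12766)
  fit <- fit_calibration(dn, refl)
  f <- tempfile(fileext = ".json")
  write_calibration_json(fit, f)
  back <- read_calibration_json(f)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$mode, fit$mode)
})
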