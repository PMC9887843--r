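test_that("build_ndvi_image encodes pixel-wise NDVI with mask propagation", {
  red <- reflectance_image(matrix(25.53, 3, 4), red_band)
  nir <- reflectance_image(matrix(39.40, 3, 4), nir_band)
  enc <- build_ndvi_image(red, nir)
  ## Burgundy pair: NDVI = 13.87/64.93, encodes to round(39767.69)
  expect_true(all(enc$codes == 39768L))
  expect_lt(abs(decode_ndvi(enc)[1, 1] - 13.87 / 64.93), 2 / 65536)
  eq <- build_ndvi_image(reflectance_image(matrix(40, 2, 2), red_band),
                         reflectance_image(matrix(40, 2, 2), nir_band))
  expect_true(all(eq$codes == 32768L))    # zero NDVI at the midpoint
  ## zero-signal pixel is masked, input masks propagate
  rv <- matrix(30, 2, 2); nv <- matrix(30, 2, 2)
  rv[1, 1] <- 0; nv[1, 1] <- 0
  m <- matrix(TRUE, 2, 2); m[2, 2] <- FALSE
  enc2 <- build_ndvi_image(reflectance_image(rv, red_band, mask = m),
                           reflectance_image(nv, nir_band))
  expect_false(enc2$mask[1, 1])
  expect_false(enc2$mask[2, 2])
  expect_true(enc2$mask[1, 2])
  expect_error(build_ndvi_image(red,
                                reflectance_image(matrix(1, 2, 2), nir_band)),
               "dimension mismatch")
})

test_that("NDVI is strictly decreasing in red reflectance", {
  set.seed(11)
  nir <- matrix(runif(64, 10, 80), 8, 8)
  red <- matrix(runif(64, 5, 60), 8, 8)
  v1 <- decode_ndvi(build_ndvi_image(reflectance_image(red, red_band),
                                     reflectance_image(nir, nir_band)))
  v2 <- decode_ndvi(build_ndvi_image(reflectance_image(red * 1.3, red_band),
                                     reflectance_image(nir, nir_band)))
  expect_true(all(v2 < v1))
})

test_that("region_stats reproduces hand-computed moments", {
  ## constant region
  s0 <- region_stats(matrix(0.4, 5, 5))
  expect_equal(s0$sd, 0); expect_equal(s0$cov, 0); expect_equal(s0$skewness, 0)
  expect_equal(s0$n, 25)
  ## {0,0,0,1}: m2 = 0.1875, m3 = 0.09375, g1 = 1.1547
  s1 <- region_stats(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(s1$mean, 0.25)
  expect_equal(s1$sd, sqrt(0.1875))
  expect_equal(round(s1$skewness, 4), 1.1547)
  ## cov = sd/mean
  s2 <- region_stats(matrix(c(8, 12), 1, 2))
  expect_equal(s2$mean, 10); expect_equal(s2$sd, 2); expect_equal(s2$cov, 0.2)
  ## zero-mean region has undefined cov
  expect_true(is.na(region_stats(matrix(c(-1, 1), 1, 2))$cov))
})

test_that("region_stats handles ROIs, masks and empty regions", {
  m <- matrix(seq(0, 1, length.out = 36), 6, 6)
  full <- region_stats(m)
  rect <- region_stats(m, c(0, 0, 6, 6))
  expect_equal(rect$mean, full$mean)
  expect_error(region_stats(m, c(4, 4, 4, 4)), "outside")
  masked <- m; masked[1:3, ] <- NA
  expect_equal(region_stats(masked)$n, 18)
  expect_error(region_stats(matrix(NA_real_, 2, 2)), "empty region")
  ## pooled mean of two disjoint ROIs equals the weighted combination
  a <- region_stats(m, c(0, 0, 3, 6))
  b <- region_stats(m, c(3, 0, 3, 6))
  u <- region_stats(m, c(0, 0, 6, 6))
  expect_equal((a$n * a$mean + b$n * b$mean) / (a$n + b$n), u$mean)
})

test_that("colorize maps codes through the LUT deterministically", {
  codes <- matrix(c(0L, 65535L, 32768L, 1000L), 2, 2)
  mask <- matrix(TRUE, 2, 2); mask[2, 2] <- FALSE
  enc <- encoded_image(codes, "ndvi", mask = mask)
  img1 <- colorize(enc)
  img2 <- colorize(enc)
  expect_identical(img1, img2)
  ## endpoints hit the first and last LUT entries
  gray <- colorize(enc, "grayscale")
  expect_equal(gray[1, 1, ], c(0, 0, 0))
  expect_equal(gray[2, 1, ], c(1, 1, 1))
  ## masked pixels render black
  expect_equal(img1[2, 2, ], c(0, 0, 0))
  expect_error(colorize(enc, "nope"), "unknown LUT")
  refl <- encode_reflectance(reflectance_image(matrix(50, 1, 1), red_band))
  expect_error(colorize(refl), "NDVI payload")
})

test_that("stats CSV emits one row per region", {
  m <- matrix(runif(16, 0.2, 0.8), 4, 4)
  st <- list(leaf1 = region_stats(m, c(0, 0, 2, 4)),
             leaf2 = region_stats(m, c(2, 0, 2, 4)))
  f <- tempfile(fileext = ".csv")
  d <- write_stats_csv(st, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 2)
  expect_equal(back$roi, c("leaf1", "leaf2"))
  expect_equal(back$mean, c(st$leaf1$mean, st$leaf2$mean), tolerance = 1e-12)
})
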