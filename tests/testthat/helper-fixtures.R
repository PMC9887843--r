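# Fixtures built in code: smooth random fields for registration tests,
# constant-patch panel images, and band shortcuts.

red_band <- band_definition("red", 620)
nir_band <- band_definition("nir", 750)

# Smooth random field in [lo, hi]: white noise blurred with a separable
# moving average so the correlation surface has a clean peak.
smooth_field <- function(h, w, seed = 1, lo = 5, hi = 95, span = 7) {
  set.seed(seed)
  x <- matrix(rnorm(h * w), h, w)
  k <- rep(1 / span, span)
  x <- t(apply(x, 1, function(r) stats::filter(r, k, circular = TRUE)))
  x <- apply(x, 2, function(c) stats::filter(c, k, circular = TRUE))
  x <- matrix(as.numeric(x), h, w)
  lo + (hi - lo) * (x - min(x)) / (max(x) - min(x))
}

# Crop two windows of a larger base so the second holds the first's
# content displaced by (dx, dy) pixels (integer shifts, no resampling).
shifted_pair <- function(base, dx, dy, size) {
  m <- (nrow(base) - size) %/% 2
  a <- base[(m + 1):(m + size), (m + 1):(m + size)]
  b <- base[(m + 1 - dy):(m + size - dy), (m + 1 - dx):(m + size - dx)]
  list(red = reflectance_image(a, band_definition("red", 620)),
       nir = reflectance_image(b, band_definition("nir", 750)))
}

# A digital image holding constant-DN patches at the given ROIs.
patch_image <- function(dns, rois, h, w, background = 30,
                        role = "red-cam") {
  px <- matrix(background, h, w)
  for (i in seq_along(dns)) {
    r <- rois[i, ]
    px[(r[1] + 1):(r[1] + r[3]), (r[2] + 1):(r[2] + r[4])] <- dns[i]
  }
  digital_image(px, "red", role)
}

# Six non-overlapping 10x10 ROIs in a 60x30 frame.
six_rois <- function() {
  cbind(row0 = rep(c(0, 15, 30), 2), col0 = rep(c(0, 15), each = 3),
        height = 10, width = 10)
}

# One-material panel for exposure-selection tests.
single_patch_panel <- function() {
  reference_panel(
    data.frame(name = "White", red_reflectance = 92.69,
               nir_reflectance = 87.62),
    rois = matrix(c(0, 0, 10, 10), 1))
}
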