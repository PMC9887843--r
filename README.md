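# ndvipipe

Tools for turning image pairs from a low-cost two-camera rig into
calibrated images of the Normalised Difference Vegetation Index (NDVI),
for plant scientists and phenotyping platforms that cannot justify a
commercial multispectral camera.  One consumer RGB camera supplies the
visible red band (centre 620 nm) through its red channel; a second
camera with the infra-red blocking filter removed, covered by a blue
plastic filter, supplies near-infrared (centre 750 nm).  The package
implements the full processing chain for such rigs and a ground-truthed
scene simulator so every stage can be exercised and validated without
hardware.

## The method

NDVI is computed pixel-by-pixel from relative reflectance (both bands in
percent, 0–100):

```
NDVI = (NIR − RED) / (NIR + RED)
```

Three instrument effects separate a raw 8-bit digital number (DN) from
the reflectance this formula needs, and each has a stage in the
pipeline:

1. **Empirical-line calibration with gamma.**  Consumer cameras apply a
   power-law gamma transform, so DN is nonlinear in radiance.  Six
   in-scene reference materials of known red/NIR reflectance (White
   92.69/87.62 % … Forest Green 4.90/5.88 %) anchor the fit

   ```
   R/100 = a · (DN/255)^γ + b
   ```

   with γ profiled over [1, 4].  A two-reference mode (brightest +
   darkest material only, γ fixed at the empirically determined de-gamma
   power 2.12766) supports field work where a full board is impractical.
   Exposure is chosen by `select_shutter_speed()`: the fastest shutter
   keeping the brightest reference below DN 240, so the full 0–100 %
   range stays calibratable.

2. **Red-leak correction.**  The blue filter in front of the NIR camera
   transmits 5–15 % of red light, additively inflating the NIR signal
   (and biasing NDVI upward at low values).  The leak fraction
   `f = S_red / (S_red + S_nir)` is integrated from the filter's
   transmission spectrum and removed: `NIR_corr = NIR_meas − f · RED`.

3. **Registration.**  The two cameras sit side by side, so their frames
   are offset by a rigid translation, estimated by normalized
   cross-correlation with sub-pixel parabolic refinement and removed by
   bilinear resampling.

Calibrated reflectance and NDVI images are stored as 16-bit grayscale
PNG: reflectance 0–100 % maps linearly to codes 0–65536, NDVI −1…+1
likewise, and the exact inverse `NDVI = code · (2/65536) − 1` recovers
values (stored codes saturate at 65535).

The synthetic-scene module renders all of this forward: a
chlorophyll-dependent leaf reflectance model (red reflectance falls with
chlorophyll, fastest near the 680 nm absorption peak; the NIR plateau is
pigment-independent), the six-material board, per-camera gamma,
saturation, noise, the filter leak and the inter-camera shift — with the
per-pixel truth returned alongside.  A wavelength-sweep verification
(`wavelength_sweep()`) mirrors the hardware validation experiment: the
band centre a camera effectively measures is found by sweeping the
matching spectrometer band until the NDVI difference is minimal.

## Worked example

Simulate a scene containing the calibration board and three leaves of
increasing chlorophyll content, then run the full pipeline:

```r
library(ndvipipe)

scene  <- make_leaf_scene(cabs = c(10, 30, 50), seed = 42)
frames <- render_scene(scene$spec)

dn  <- extract_panel_means(frames$red, scene$panel, "red")
fit <- fit_calibration(dn, scene$panel$materials$red_reflectance)
fit
#> Empirical-line calibration (six-reference, n = 6)
#>   R/100 = 1.00004 * (DN/255)^2.12419 + -0.00032
#>   gamma fitted, rmse 0.0216%
```

The fitted exponent 2.124 recovers the camera's gamma (the scene was
rendered with 2.12766; sensor noise accounts for the difference), and
the gain/offset are the identity, as they must be for a camera whose
panel DNs were generated from the panel's own reflectances.

```r
rois <- list(leaf10 = scene$leaf_rois[1, ] + c(3, 3, -6, -6),
             leaf30 = scene$leaf_rois[2, ] + c(3, 3, -6, -6),
             leaf50 = scene$leaf_rois[3, ] + c(3, 3, -6, -6))
cfg <- run_config(frames$red, frames$nir, scene$panel,
                  analysis_rois = rois, leak_fraction = 0.1)
res <- run_pipeline(cfg)
#> alignment: shift dx +2.00, dy -1.00 (score 0.978)
#> ndvi: 15288/15642 valid pixels, code range [0, 43501]
res$stats$leaf30
#> <region_stats> n = 196, mean = 0.1623, sd = 0.0151, cov = 0.0932, skewness = -0.1129
```

The estimated shift matches the simulated mount offset (+2, −1) px, and
the per-leaf NDVI means (0.0333, 0.1623, 0.2803) agree with the scene
truth (0.0338, 0.1606, 0.2804) to well within 0.01 — the whole chain of
calibration, alignment and leak correction closes on the ground truth.

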