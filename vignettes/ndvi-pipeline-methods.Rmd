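---
title: "Methods: dual-camera NDVI imaging with empirical-line calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-camera NDVI imaging with empirical-line calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndvipipe)
```

This vignette documents the models and procedures behind `ndvipipe`, the
assumptions they rest on, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real imagery.

## The measurement model

A two-camera rig measures NDVI indirectly.  Each camera reports 8-bit
digital numbers (DN); the quantity NDVI is defined on is relative
reflectance, in percent:

$$\mathrm{NDVI} = \frac{R_{NIR} - R_{RED}}{R_{NIR} + R_{RED}},
\qquad R \in [0, 100]\,\%.$$

The package treats the DN-to-NDVI chain as three physically distinct
corrections, each fitted or parameterised independently.

### Empirical-line calibration with a gamma exponent

Consumer cameras gamma-encode: DN is proportional to (radiance)^(1/γ)
with γ near 2.2.  With six in-scene reference materials of known
reflectance, `fit_calibration()` fits

$$R/100 = a\,(DN/255)^{\gamma} + b$$

by least squares.  The exponent is profiled: for any candidate γ the
gain $a$ and offset $b$ solve a linear system in closed form, leaving a
smooth one-dimensional objective that is minimised by golden-section
search on γ ∈ [1, 4].  This avoids the line-search fragility of general
quasi-Newton methods on a 3-parameter surface with strong γ–$a$
correlation, and it makes the linear-camera limit (γ → 1, e.g. a
narrowband instrument without gamma encoding) a clean boundary case.

The fitting direction is DN → R, the direction used at application
time; the alternative (fit DN as a function of R, then invert) was not
stated by the original method description and the applied direction is
the one whose residuals matter for the output.

Two-reference mode supports field protocols where only the brightest
(White) and darkest (Forest Green) materials are deployed.  Two points
cannot constrain three parameters, so γ is fixed — by default at
2.12766, the de-gamma power determined empirically for this camera
family — and $a, b$ solve the 2×2 system exactly.  The fixed power is a
user-overridable default because the de-gamma exponent of another
camera, or even of the second (filtered) camera of the same rig, need
not be identical; with a full board the six-reference fit should be
preferred, and the test suite checks it never fits the panel worse than
the two-reference mode.

Patch statistics use the mean DN of each region of interest after
eroding a 10 % margin per side (tolerates imprecise ROI placement and
resampling edges) and discarding pixels with DN ≥ 250 (saturated pixels
carry no radiometric information).  A patch mean at or above 240
triggers a warning: exposure should be selected, via
`select_shutter_speed()`, as the fastest shutter keeping the brightest
reference below DN 240, since a clipped bright reference makes the top
of the reflectance range uncalibratable.

### Red-leak correction

The NIR camera's blue plastic filter transmits a small fraction (5–15 %)
of red light.  Modelling the contamination as additive in reflectance,

$$R_{NIR}^{meas} = R_{NIR}^{true} + f\,R_{RED},$$

`estimate_leak_fraction()` computes $f$ as the red share of the
filtered camera's band signal,
$f = S_{red}/(S_{red} + S_{nir})$ with
$S_{band} = \sum_\lambda I(\lambda)\,\rho(\lambda)\,T(\lambda)$
integrated over each band (centre ± FWHM/2, 1 nm grid, 400–900 nm), and
`correct_nir_leak()` subtracts $f\,R_{RED}$, clamping at zero with
clamped pixels flagged.

Two ordering decisions were open:

* **Leak correction operates in reflectance space, after calibration.**
  The contamination is physically additive in radiance; reflectance is
  proportional to radiance per band, while DN is not (gamma), so
  correcting DNs would entangle the leak with the power law.
* **Correction happens after alignment.**  The contamination arises in
  the NIR camera's frame, but subtracting $f\,R_{RED}$ requires the red
  value *at the same scene point*.  Aligning first and then correcting
  uses exactly that value; the reverse order (correct, then align) would
  subtract red values displaced by the mount offset and leave edge
  artefacts at reflectance boundaries.
* **Panel references for the NIR camera are leak-adjusted.**  The
  in-scene panel is imaged through the same filter, so its NIR-channel
  signal also contains the leak.  Calibrating the NIR camera against
  pure tabulated NIR reflectances would fold a material-dependent share
  of the leak into the fit (the board's materials have different
  red:NIR ratios, so no single gain absorbs it).  `run_pipeline()`
  therefore calibrates the NIR camera against $R_{NIR} + f\,R_{RED}$ of
  each material: the calibrated NIR image is then total in-band signal,
  and the subsequent subtraction of $f\,R_{RED}$ removes the leak
  exactly.  This is what lets the noiseless end-to-end test close on
  the ground truth to within 0.01 NDVI.

### Registration

The cameras share a rigid mount, so a pure translation is an adequate
motion model; affine or projective models would add parameters without
a physical source of shear at fixed focus.  `estimate_shift()`
exhaustively evaluates normalized cross-correlation over integer shifts
within a search radius (default 10 px, bounded by a quarter of the
image so the overlap stays informative) and refines each axis by a
parabolic fit through the correlation peak and its two neighbours,
clamped to ±0.5 px.  The test suite requires recovery within 0.5 px
over 50 random shifts up to ±20 px and under 20 dB additive noise.
`apply_shift()` resamples bilinearly; pixels drawing on out-of-frame or
invalid sources are masked.  Note that bilinear resampling is exact on
affine images but smooths general content, so a fractional shift and
its inverse compose to an interior identity only on such images — the
tests check exactly that.

## Encoding

Reflectance 0–100 % maps linearly onto 0–65536 and NDVI −1…+1 onto the
same range; decoding is the exact inverse
$\mathrm{NDVI} = code \cdot (2/65536) - 1$.  The nominal top of the
scale, 65536, does not fit an unsigned 16-bit integer: stored codes
saturate at 65535 (one code width below the nominal endpoint, an error
of 1.5·10⁻⁵ in NDVI) while the decode formula keeps denominator 65536
so that the nominal endpoint decodes to exactly +1.  Rounding is
half-away-from-zero — deterministic and platform-independent, unlike
banker's rounding.  Undefined pixels ($R_{NIR}+R_{RED} \le 10^{-6}$ %)
are masked rather than given an arbitrary value, encoded as 0, and
tracked in a mask sidecar; region statistics exclude them.

Outputs are 16-bit grayscale PNGs with a JSON sidecar (payload type,
scale, band, mask file).  The 16-bit PNG encoder is implemented in the
package (grayscale, deflate via the zlib stream, CRC-32 per chunk);
files are read back with `png::readPNG`, an independent implementation,
and the round trip is asserted bit-exactly in the tests.

## The synthetic scene generator

`render_scene()` emulates, per pixel: ground-truth reflectance from the
layout (panel materials use the packaged six-material table; leaves use
the leaf model at the camera band centres), the additive filter leak in
the NIR frame, the rigid inter-camera translation, per-camera
shutter-proportional gain, the gamma power law, additive Gaussian DN
noise, and 8-bit rounding with saturation.  Identical seeds give
byte-identical frames.

The leaf model is a deliberately simple parametric stand-in for a full
plate-model (radiative-transfer) simulation.  For λ ≤ 700 nm,

$$R(\lambda, c) = 2 + 48\,e^{-k(\lambda)\,c},\qquad
k(\lambda) = 0.08\,e^{-((\lambda-680)/45)^2},$$

with $c$ the chlorophyll a+b content in µg cm⁻²; for λ ≥ 750 nm the
reflectance is a pigment-independent 47 % plateau, with a linear
red-edge blend on (700, 750) nm.  This reproduces the only spectral
properties the pipeline's logic depends on: red reflectance decreases
monotonically with chlorophyll, the sensitivity peaks at the 680 nm
absorption maximum and fades with spectral distance from it, the NIR
plateau is flat and chlorophyll-independent from 750 nm so the NIR band
choice is immaterial across 750–800 nm, and spectral NDVI at
(620, 750) increases strictly over the 0–60 µg cm⁻² sweep.  The
constants (2 % floor, 50 % zero-chlorophyll ceiling, 47 % plateau,
$k_0 = 0.08$, 45 nm width) are fixture choices tuned to those
qualitative properties, not fitted to any measured spectra.  The
red-edge blend ends at 750 nm rather than earlier because the
wavelength-sweep verification depends on the plateau beginning where
real leaf spectra flatten; an earlier plateau would make shorter NIR
wavelengths spuriously equivalent.

Generator defaults are the rig's nominal operating conditions, chosen
once: irradiance 800 µmol m⁻² s⁻¹; camera shutters 400 µs (red) and
2500 µs (NIR) with unit gain at those settings; gamma 2.12766; DN noise
sd 1.5 (additive after gamma, before rounding — read noise dominates at
these signal levels, so photon noise is not modelled separately); leak
fraction 0.10, the midpoint of the filter's stated 5–15 % red
transmission; inter-camera shift (2, −1) px; background reflectance
10 %/10 %.  The NIR camera's gain additionally carries an in-band
filter throughput of 0.85 (the filter passes over 80 % of NIR); without
it a correctly exposed NIR frame would saturate the White patch once
the leak is added.  Calibration cancels the factor, since panel and
scene share it.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: vignetting and other spatially
varying gain, lens distortion (real registration residuals are not pure
translations), Bayer-channel crosstalk beyond a scalar band value,
BRDF/angular effects on the board, mixed pixels at leaf boundaries,
specular highlights, and canopy geometry.  Agreement statistics
reported for real plants by hardware studies (regression R², per-leaf
skewness of NDVI histograms) depend on such effects and on the actual
plant material; they cannot be reproduced from synthetic scenes and are
not asserted anywhere in this package.

## The verification sweep

`wavelength_sweep()` mirrors the hardware validation experiment: given
per-sample camera NDVI and spectrometer spectra, the swept band's
wavelength varies (red 600–700 nm or NIR 700–800 nm, default step
10 nm, endpoint inclusive, 1 nm available) while the other band is
fixed, and each candidate is scored by the mean absolute percentage
difference, $\mathrm{mean}_i\,100\,|{\rm NDVI}^{cam}_i -
{\rm NDVI}^{spec}_i(\lambda)|/|{\rm NDVI}^{spec}_i(\lambda)|$.  The
percentage difference was not given as a formula in the original
description; the absolute per-sample form with the spectrometer value
as denominator was chosen because the spectrometer is the reference
instrument, and per-sample averaging matches the error bars such
experiments report.  Samples with a spectrometer NDVI of exactly zero
at a candidate wavelength are excluded there (the relative difference
is undefined) with a warning.  Ties in the argmin break to the shortest
wavelength, deterministically — this matters on the NIR plateau, where
all wavelengths from 750 nm score identically and the sweep reports
750.

`compare_to_reference()` supplies the companion agreement metrics:
ordinary least squares of camera on reference, squared Pearson
correlation, and the population standard deviation of the differences.

## Problem sizes and tolerances

The test-suite experiments use scene sizes and replicate counts chosen
to exercise every code path at comfortable margins: 24-leaf sweeps on
~190×160 px scenes for end-to-end verification, 96×96 px windows with a
±20 px search for the 50-shift registration study, 100 random
parameter draws for calibration recovery (γ within 10⁻³ noiseless,
0.05 under DN quantization; predictions within 0.1 % reflectance), and
a 0.01 absolute NDVI budget for the noiseless end-to-end identity —
the sum of DN-quantization effects through calibration stays under half
of that.  Statistics use population (not sample) moments, matching
their descriptive per-image use; skewness of a zero-variance region is
defined as 0; the coefficient of variation is flagged undefined when
|mean| < 10⁻¹².

## Known limitations

* Translation-only registration; an affine/feature-based mode is a
  natural extension point but is not implemented.
* No vignetting model or correction anywhere in the pipeline.
* The leak model is a single scalar fraction; a spectrally resolved
  correction would need per-wavelength camera sensitivities.
* The 16-bit encoder writes only grayscale PNG; floating-point TIFF and
  colour management are out of scope.
* Whether green/blue crosstalk onto the red Bayer channel should also
  be corrected is left open (it is expected to be small and is not
  simulated separately).
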