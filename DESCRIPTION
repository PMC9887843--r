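Package: ndvipipe
Title: Dual-Camera NDVI Imaging Pipeline with Empirical-Line Reflectance
    Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for producing Normalised Difference Vegetation Index
    (NDVI) images from low-cost two-camera rigs in which one RGB camera
    supplies the visible red band and a second, filtered camera supplies
    the near-infrared band.  Implements gamma-aware empirical-line
    calibration of 8-bit digital numbers to relative reflectance using a
    six-material reference panel, correction of the red-light leak through
    the NIR filter, translation-based registration of the two camera
    frames, pixel-wise NDVI computation with 16-bit encoding, and a
    wavelength-sweep verification of camera NDVI against spectrometer
    spectra.  A ground-truthed synthetic scene generator (chlorophyll
    dependent leaf spectra, reference panel, camera gamma/saturation/noise
    model and simulated spectrometer) allows the whole pipeline to be
    exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
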