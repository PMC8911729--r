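Package: nanosaxs
Title: Scanning-SAXS Nanomechanical Imaging of Fibrous Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces 2D small-angle X-ray scattering (SAXS) detector frames
    to calibrated radial I(q) and azimuthal I(chi) profiles, fits the
    meridional collagen D-period peak and the broad equatorial
    interfibrillar peak to map nanoscale structural parameters over a
    scan grid, and applies subset-based digital image correlation to
    diffraction-contrast intensity maps from successive load steps to
    obtain spatially resolved collagen fibril strain and reorientation.
    Includes a forward simulator of Pilatus-like scattering frames and
    deformed scan pairs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
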