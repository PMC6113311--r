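Package: subslicer
Title: Dual-Energy Sub-Slice Reconstruction for Serial Block-Face SEM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of keV electron backscattering in
    stained, resin-embedded biological specimens, and reconstruction of
    sub-slice heavy-atom stain distributions from serial block-face
    scanning electron microscopy (SBEM) images acquired at two landing
    energies. A trajectory-level Monte Carlo engine (screened-Rutherford
    elastic scattering, Joy-Luo continuous slowing down) calibrates a
    depth-response matrix linking stain density in subsurface layers to
    backscattered-electron signal at each energy; per-pixel inversion of
    dual-energy image stacks then recovers stain density in two layers
    per physical cut, doubling z-resolution relative to the microtome
    cutting increment. Includes voxel phantom generators, electron-dose
    budgeting, and TIFF/JSON stack input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
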