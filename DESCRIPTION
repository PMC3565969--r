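Package: rbcphase
Title: Red Blood Cell Morphometry from Off-Axis Quantitative Phase Interferograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for label-free blood testing by quantitative
    phase imaging. Reconstructs unwrapped, background-corrected phase maps from
    off-axis interferograms by Fourier (Hilbert) demodulation and quality-guided
    unwrapping, segments individual red blood cells with a label-equivalence
    connected-component labeller, and computes per-cell morphological
    parameters (projected area, volume, Monge surface area, sphericity,
    minimum cylindrical diameter, and extended shape and height statistics)
    together with population indices (MCV, RDW, distributions). Includes a
    synthetic phantom generator that renders ground-truthed off-axis
    interferograms of red blood cell scenes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
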