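Package: osteem
Title: In Situ Quantification of Osteogenic Mineralization from 2D
    Fluorescence Spectra of Alizarin Red S
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying matrix mineralization in osteogenic
    cell cultures from excitation-emission matrix (EEM) fluorescence
    spectra of Alizarin Red S (ARS) staining. Provides EEM containers
    with scatter masking, saddle-point fingerprinting of the ARS-calcium
    complex on the 2D spectral surface, the normalized 670/560 nm
    ratiometric mineralization index read at 420 nm excitation, linear
    concentration calibrations for absorbance and fluorescence channels,
    a four-method (absorbance/fluorescence x in-situ/extract) fold
    induction comparison, and a seeded synthetic spectra generator with
    known ground truth for validating the whole pipeline, including
    opaque graphene-oxide substrates where in-situ absorbance fails.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
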