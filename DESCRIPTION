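Package: nanomech
Title: Nanomechanics and Morphometry of Epithelial Cells on Nanofibrous Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing epithelial cell sheets grown
    on electrospun nanofibrous culture substrates. Fits AFM force-indentation
    curves with an adhesive (JKR) contact model extended by a membrane-spring
    term to extract Young's modulus, membrane stiffness, contact point and
    adhesion energetics; quantifies nanofiber membranes (fiber diameter, pore
    size, FFT orientation anisotropy, RMS roughness); computes cell and
    nucleus morphometrics and junction-protein intensity fold changes from
    two-channel images; and measures scratch-wound closure kinetics. Ships
    synthetic-data generators with ground truth for every input so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
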