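Package: ovoquant
Title: Quantitative Analysis of In Vivo Drosophila Oogenesis Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying egg-chamber development from intravital
    fluorescence microscopy of the Drosophila ovary. Estimates per-stage
    developmental durations from fixed-sample stage-frequency surveys,
    constructs and inverts exponential standard growth curves, segments
    nuclei in 3D confocal stacks (Gaussian blur, Otsu threshold,
    morphological refinement, connected-component labelling), quantifies
    normalized fluorescence in named egg-chamber regions (yolk uptake into
    the oocyte, histone redistribution during nurse-cell dumping), aligns
    live growth traces to the standard curve, and computes follicle-cell
    rotation kinematics. A synthetic-data generator produces surveys, image
    phantoms, compartmental dumping series and rotation tracks with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
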