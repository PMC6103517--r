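Package: mtocQuant
Title: Quantitative Fluorescence Imaging of Apical and Centrosomal
    Microtubule Organizing Centers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify tissue-specific protein depletion, apical
    enrichment, and microtubule plus-end (EB1 comet) dynamics at
    non-centrosomal microtubule organizing centers in fluorescence
    micrographs of the C. elegans embryonic intestinal primordium.
    Provides calibrated S4 containers for z-stacks and time-lapse movies,
    line-intensity profiling across the apical midline, background and
    autofluorescence corrected percent-depletion estimates, circular-ROI
    centrosome intensities, automated focus and nucleus counting,
    kymograph construction with slope-based comet speed estimation,
    comet crossing counts, and the Welch/paired t statistics used to
    compare genotypes. A synthetic-microscopy generator with known ground
    truth makes every stage of the pipeline testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, EBImage, tiff, jsonlite, yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization
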