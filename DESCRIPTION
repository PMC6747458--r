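Package: retinaquant
Title: Synthetic Benchmarking and Quantification of Microglia and
    Retinal Ganglion Cells in Retinal Whole Mounts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic single-channel fluorescence fields of
    Iba-1-like ramified microglia and Brn3a-like retinal ganglion cell
    nuclei with known ground truth, implements the normalize-threshold-
    segment-deduplicate cell-counting algorithm used for retinal whole
    mounts, automated morphometry (soma area, arbor area), percent-area
    quantification, and the nonparametric group-comparison statistics of
    a multi-group paired-eye ocular-hypertension study design, so the
    full quantification pipeline can be exercised and validated
    end-to-end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
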