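Package: invadex
Title: Quantitative Analysis of Tumor-Cell Local Invasion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring how far cancer cells have scattered into
    surrounding tissue. Implements the nearest-neighbor-distance Local
    Invasion Index (LII) with border correction for tissue-microarray
    cores, nuclei/cytokeratin segmentation of immunofluorescence images,
    invading-cell counting in 3D culture assays, the cellularity-corrected
    DCIS index for intraductal xenograft sections, per-study exact
    odds-ratio meta-analysis of 2x2 contingency tables, kymograph-based
    membrane-ruffle frequency and speed quantification, leading-edge band
    intensity measurement, and a fold-change/p-value volcano screen for
    curated gene lists. Every analysis is paired with a synthetic-data
    generator that plants known ground truth, so the full pipeline can be
    validated end to end without access to the original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
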