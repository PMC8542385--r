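Package: keragg
Title: High-Content Quantification of Keratin Aggregates in Reporter
    Keratinocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated image analysis for GFP-K14 reporter
    keratinocyte assays: per-cell keratin aggregate detection from
    two-channel fluorescence fields (watershed nuclei segmentation,
    component-based Voronoi cell regions, difference-of-Gaussians puncta
    calling), plate-level hit calling for kinase-inhibitor screens with a
    DMSO baseline and fractional-reduction cut-off, dispase dissociation
    fragment counting, and LIVE/DEAD viability counting.  Includes a
    deterministic synthetic-field generator with exact ground truth for
    validation, plus a command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
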