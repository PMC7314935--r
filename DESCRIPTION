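Package: scratchquant
Title: Automated Quantification of Scratch Wound-Healing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated analysis of in vitro scratch (wound-healing)
    assay images. Phase-contrast images of cell monolayers are segmented into
    cell and media pixels by gradient-magnitude binarization, summarized as
    column-wise black/white pixel-ratio profiles, re-centered on the scratch
    disruption at the initial time point, and averaged across replicates to
    yield gap-closure endpoints (gap width, percent closure, cell-to-space
    ratio). Companion fluorescence readouts (Laplacian-of-Gaussian spot
    counting in a region of interest, immunofluorescence area fraction per
    nucleus), group statistics (ANOVA with Tukey HSD, pairwise t-tests), a
    synthetic image generator with planted ground truth, and a batch pipeline
    driven by a CSV manifest are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
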