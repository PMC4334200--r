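Package: atgscreen
Title: Autophagy Puncta Quantification and SSMD Hit Calling for
    High-Content RNAi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-content RNAi screens of autophagy
    in primary muscle cultures. Generates ground-truthed synthetic
    multi-channel fluorescence fields and simulated replicate 384-well
    plates; quantifies autophagy from images (phalloidin-based muscle
    segmentation, top-hat granularity and quadtree RATS puncta detection,
    puncta-area per muscle-area index, Manders overlap colocalization,
    autophagic-flux ratios); and scores screens by plate-median log
    normalization, the UMVUE estimator of the strictly standardized mean
    difference (SSMD), and two-tier per-gene hit calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
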