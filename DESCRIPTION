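Package: segeval
Title: Boundary-Map Segmentation Scoring for Connectomics Challenges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring of 2D neurite segmentations represented as binary
    boundary maps, as used in electron-microscopy segmentation challenges.
    Converts boundary maps to segmentations by connected components with
    the singleton-border-pixel convention, computes foreground-restricted
    Rand and information-theoretic split, merge and F-scores from a sparse
    contingency table, performs non-merging border thinning and border
    dilation, threshold sweeps for probabilistic boundary maps, stack-level
    aggregation with uncertainty, Wilcoxon signed-rank comparisons and
    Spearman ranking-robustness analysis, plus a synthetic Voronoi
    ground-truth generator with controlled split/merge/border-width
    perturbations and a command-line interface over multi-page TIFF or PNG
    stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
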