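Package: ihcnorm
Title: Stain Normalization and Nuclei Classification for Immunohistochemistry Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Color normalization for hematoxylin/DAB immunohistochemistry (IHC)
    images built from Beer-Lambert optical-density transforms, STRESS random-spray
    local contrast stretching, automatic (Macenko) and sparse non-negative
    matrix-factorization stain separation, structure-preserving color
    normalization, robust self-sparse fuzzy-clustering segmentation of nuclei
    versus background, and a nuclei/background merge. Includes the quaternion
    structural similarity (QSSIM) image-quality metric, an unsupervised
    immunopositive/immunonegative pixel classifier based on automatic color
    deconvolution, and a synthetic IHC scene generator with full ground truth for
    oracle-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    yaml,
    Rcpp,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
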