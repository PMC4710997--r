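Package: dwisr
Title: Sparse-Representation Denoising of Diffusion-Weighted MR Image
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Patch-based denoising of three-dimensional diffusion tensor
    imaging (DTI) data by sparse representation over dictionaries learned
    with K-SVD from groups of adjacent slices, exploiting the context
    redundancy of neighbouring slices in a diffusion-weighted volume.
    Includes an error-constrained L1 (Lasso homotopy) sparse coder, a
    closed-form overlapping-patch aggregation step, a DTI phantom
    simulator (Stejskal-Tanner forward model with Rician noise),
    log-linear diffusion tensor fitting, fractional-anisotropy maps and
    FA error metrics, and NIfTI/FSL gradient-table input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
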