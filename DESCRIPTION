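Package: contrastPCA
Title: Contrastive PCA with Spatial Kernel and Functional Basis Extensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contrastive principal component analysis solved as a Rayleigh
    quotient generalized eigenproblem, with two extensions: a kernel-weighted
    spatial form (k-rhoPCA) that contrasts a spatially registered target
    expression matrix against a non-spatial background, and a functional form
    (f-rhoPCA) that solves the contrastive eigenproblem in the space of basis
    function coefficients to find contrastive modes of variation in curves.
    Includes count-matrix preprocessing (filtering, depth normalization,
    median-of-ratios size factors), synthetic data generators with planted
    contrastive structure, readers and writers for Matrix Market and
    delimited formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
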