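Package: kernelField
Title: Three-Dimensional Kernel Projection Classifiers for Protein
    Sequence Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies protein domains (tertiary structural classes) and
    membrane protein types from amino-acid composition by projecting
    samples into a low-dimensional (default three-dimensional) kernel
    space with kernel principal component analysis or kernel generalized
    discriminant analysis, then deciding the class either by K-nearest-
    neighbour vote or by a Coulomb-style class-intensity model in which
    every projected training sample acts as a point charge of magnitude
    1/n_C and the class with the largest inverse-square field intensity at
    the query wins. Includes range scaling, a leave-one-out
    cross-validation harness, a two-stage hierarchical pipeline for
    membrane-protein typing, seeded synthetic-data generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr
biocViews: Classification, Proteomics, DimensionReduction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
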