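Package: fatebin
Title: Pseudotime-Binned Differential Expression and Branch Divergence for
    Two-Genotype Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for comparing differentiation between two genotypes in
    single-cell RNA-seq of branching lineages such as the intestinal
    epithelium. Provides loading of 10x-style sparse count triplets,
    size-factor log-normalization and principal component reduction, Leiden
    clustering with marker-overlap cell-type annotation, two-proportion
    z-tests of cell-type composition, a minimum-spanning-tree principal
    graph with geodesic pseudotime rooted at the stem compartment,
    per-pseudotime-bin negative-binomial regression of expression on
    genotype, and branch-restricted polynomial fits with a between-genotype
    slope-divergence test. Includes a seeded negative-binomial simulator of
    branching two-genotype data with known cell types, pseudotime and
    planted genotype-by-pseudotime effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
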