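Package: smallherd
Title: Genomic and Pedigree Evaluation of Dairy Cattle in Very Small Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of dairy cattle breeding programmes with
    weakly connected, very small herds, and BLUP genetic evaluation of the
    resulting populations. Provides a sequentially Markov coalescent
    generator for neutral founder haplotypes, forward-in-time gene dropping
    with phenotypic sire selection, a zero-truncated Poisson herd-structure
    model, pedigree (A) and VanRaden genomic (G) relationship matrices with
    a sparse Meuwissen-Luo inverse, and Henderson mixed-model equations for
    PBLUP and GBLUP with the herd effect excluded, fixed, or random.
    Replicated experiments return tidy accuracy tables and ggplot2 figures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
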