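Package: microrepro
Title: Reproducibility and Stability Analysis for Replicated Stool
    Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the technical reproducibility and temporal stability
    of stool microbiome measurements from replicated collection designs.
    Computes rarefied alpha diversity (richness, Chao1, Shannon, Faith's
    phylogenetic diversity), weighted and unweighted UniFrac distances with
    principal coordinates, variance-component intraclass correlation
    coefficients (ICC) with permutation inference, PERMANOVA-style
    distance-based R-squared, temporal-stability ICCs between delayed-freezing
    time points, and the abundance-reproducibility trend regression. Includes
    a hierarchical log-normal-multinomial study simulator with known
    ground-truth variance components for end-to-end validation of replicated
    collection-media designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    phyloseq,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
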