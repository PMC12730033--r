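Package: phenodiv
Title: Phenotypic Divergence and Genetic-Parameter Analysis for Plant Germplasm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phenotypic variability in balanced
    germplasm trials laid out as completely randomized designs. Computes
    seed and seedling physiology indices (thousand-seed weight,
    germination percentage, Maguire's germination speed index, mean
    germination time, biomass density, seed vigor index), per-trait
    variance components and genetic parameters (broad-sense
    repeatability, coefficients of genetic and environmental variation),
    Scott-Knott grouping of treatment means, generalized Mahalanobis D2
    and standardized Euclidean divergence matrices, Tocher optimization
    and UPGMA clustering with Mojena's dendrogram cutoff, Singh's
    relative trait contributions, canonical variate analysis, and
    genotype-ideotype distance selection. A synthetic-data generator
    with known ground-truth parameters supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
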