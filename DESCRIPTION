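Package: genogeo
Title: Quantifying the Similarity Between Genes and Geography with
    Procrustes-Superimposed PCA Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how closely population-genetic structure
    mirrors geography. Standardizes diploid SNP genotype matrices, computes
    eigenvalue-scaled principal components, superimposes the PC1-PC2 map onto
    population geographic coordinates by Procrustes analysis (similarity
    statistic t0 with a population-label permutation test), runs leave-one-out
    population-exclusion and marker-subsampling robustness analyses, and
    estimates multi-locus Weir-Cockerham FST. Includes quality-control filters
    (missing-data and iterative PCA-outlier removal), an equal-area Gall-Peters
    projection for worldwide coordinates, and generators of synthetic
    isolation-by-distance and Balding-Nichols genotype datasets with known
    geographic truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
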