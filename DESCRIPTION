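Package: pathwayvc
Title: Variance-Component Pathway Analysis of Gene Expression in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway and gene-set association analysis for family data via
    similarity-kernel variance components. Expression profiles restricted to a
    pathway's genes are turned into individual-by-individual similarity
    matrices (16 metrics, including correlation, extended Jaccard,
    Bhattacharyya, divergence and Euclidean), each added as an extra variance
    component to a polygenic mixed model whose null covariance is the
    pedigree-derived expected relatedness (2*phi) matrix, and tested with a
    boundary likelihood-ratio test. Includes expression preprocessing
    (shift/log2, quantile normalization, covariate residualization,
    representative-probe selection, unit scaling), recursive pedigree kinship,
    maximum-likelihood variance-component fitting, scan orchestration with
    Bonferroni correction and inflation diagnostics, and a family-data
    simulator with known heritability and known causal pathways for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, limma, jsonlite
Suggests: testthat (>= 3.0.0), fgsea, igraph, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
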