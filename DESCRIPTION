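Package: ddgnet
Title: Cell Type-Specific Network Prioritization of Differentiation Driver Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing differentiation driver genes
    (DDGs) from single-cell transcriptomes of genetically diverse mouse
    populations. Implements per-cluster mean-expression pseudobulk with a
    CPM/variance-stabilizing/quantile normalization chain, minimum-spanning-tree
    trajectory inference with pseudotime cell-type boundaries, negative-binomial
    spline tests for boundary-dynamic genes, signed weighted co-expression module
    detection with iterative kME refinement, Bayesian network structure learning
    (max-min hill climbing), three-step-neighborhood hypergeometric enrichment,
    founder-haplotype eQTL scans with permutation LOD thresholds,
    cell-composition tests on arcsine-square-root proportions, and
    GWAS-colocalization intersection reports. Includes a fully specified
    synthetic-data generator with serialized ground truth for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    limma,
    MASS,
    methods,
    splines,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
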