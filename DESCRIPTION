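Package: endoclust
Title: EHR-Derived Endometriosis Sub-Phenotype Clustering and
    Cluster-Stratified Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives endometriosis sub-phenotype clusters from binary
    ICD-derived clinical features by spectral clustering with empirical
    model selection (silhouette, distortion, evenness over K = 2-20),
    characterizes clusters by two-population proportion z-tests, transfers
    cluster labels to genotyped cohorts with a k-nearest-neighbour
    classifier, and runs cluster-stratified candidate-locus case-control
    association with covariate-adjusted logistic score tests,
    DerSimonian-Laird random-effects meta-analysis across ancestry strata,
    a pooled positive control and a size-preserving randomized negative
    control. Includes a synthetic cohort generator with planted subtypes
    and subtype-specific genetic effects so the full pipeline is testable
    without access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    cluster,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
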