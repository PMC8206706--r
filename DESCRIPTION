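Package: traitscape
Title: Adaptive Walks with Evolving Trait Correlations on Empirical Trait
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a low-dimensional PCA fitness landscape ("trait-scape")
    from multi-genotype phenotypic trait tables, simulates adaptive walks of
    populations whose individuals carry both trait values and heritable
    pairwise trait correlations, and analyses the emergent population types.
    Includes configurable historical-bias initialization (random, ancestral
    or evolved standing correlations), a fitness-weighted Wright-Fisher-style
    resampling engine, a replicate-level phenotype census with
    silhouette-selected UPGMA clustering, and a from-scratch multiscale
    bootstrap implementation of approximately unbiased (AU) cluster p-values
    with correlation-space ordination and convex hulls.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
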