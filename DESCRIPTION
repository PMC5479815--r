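Package: tempoclust
Title: Temporal Archetype Analysis of Stage-Series RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of time-course bulk RNA-seq over organoid growth
    stages: RPKM quantification and expression-based gene trimming,
    per-gene log2 normalization, seeded multi-restart K-means clustering
    into temporal archetypes (late rise, early rise, flat, early drop),
    hierarchical clustering of stages, cross-replicate cluster matching
    and consensus gene sets, genewise negative-binomial GLM
    likelihood-ratio tests across stages with a replicate covariate and
    Benjamini-Hochberg FDR control, and one-sided hypergeometric gene-set
    enrichment against GMT category collections. Includes a
    negative-binomial stage-series simulator with known archetype labels
    and a planted enriched category, so the whole pipeline is testable
    end to end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    fgsea,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    edgeR,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
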