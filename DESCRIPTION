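Package: coremicro
Title: Compositional Core-Microbiome and Community Assembly Analysis for
    Host-Associated 16S Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing host-associated amplicon (16S rRNA)
    bacterial communities against their source environment. Provides
    feature-table input/output (TSV and BIOM-JSON) with organelle,
    unclassified and low-frequency filtering, taxonomy collapsing,
    seeded rarefaction and prevalence summaries; alpha diversity
    (observed features, Faith's phylogenetic diversity) and beta
    diversity (Jaccard, Bray-Curtis, unweighted and generalized
    UniFrac) with principal-coordinate ordination and one-way
    permutational multivariate analysis of variance; Monte-Carlo
    Dirichlet centered-log-ratio (clr) differential abundance with
    expected Benjamini-Hochberg p-values and effect sizes; a
    cross-study core-microbiome identification procedure based on
    log2 abundance differences against the non-core community with
    a Monte-Carlo Dunnett test; community assembly categorization
    (prevalence/abundance classes, stability, membership sets);
    cross-study harmonization (compartment combination, genus counts
    per phylum, Dunn's test with compact letters, Spearman taxa
    correlation); a seeded multi-study synthetic community generator
    with planted ground truth; and a configuration-driven pipeline
    runner with provenance tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    biomformat,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
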