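Package: phylosym
Title: Cross-Kingdom Phylosymbiosis and Co-Occurrence Analysis for
    Paired Microbiome Count Tables
Version: 0.1.0
Authors@R:
    person("phylosym", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing phylosymbiosis and cross-kingdom
    covariation in paired fungal and bacterial amplicon count tables.
    Provides strict readers and writers for feature tables, taxonomy,
    sample metadata, diet tables and host trees; compositional
    normalization (rarefaction, centred log-ratio transform, Aitchison
    distances, taxonomic agglomeration, species-level merging, alpha
    diversity); phylogenetic-signal testing with Abouheif's Cmean and
    permutation nulls; sequential (Type-I) PERMANOVA; Procrustes and
    PROTEST comparison of ordinations with bootstrap sweeps across
    taxonomic ranks; Mantel tests and diet analyses; Spearman-threshold
    co-occurrence networks with structural traits and label-permutation
    null tests; a ground-truth synthetic-data generator that simulates
    phylogenetically structured, coupled two-kingdom communities on a
    host phylogeny; and a pipeline runner with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
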