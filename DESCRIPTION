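Package: evoranker
Title: Disease-Gene Prioritization from Clade-Wise Phylogenetic Profiling and Phenotype Semantic Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes patient candidate genes for rare Mendelian disease by
    linking each candidate to the patient's phenotype through two evidence
    channels: genes that co-evolve with the candidate across eukaryotic clades
    (normalized phylogenetic profiling, Pearson correlation of per-species
    conservation profiles) and genes that interact with it in a STRING-style
    functional network. Each channel is tested with a one-sided two-sample
    Kolmogorov-Smirnov statistic against the full list of genes ranked by
    Lin/best-match-average semantic similarity to the patient's HPO terms, and
    the channel p-values are combined with Fisher's method (Simes' method as an
    alternative). Includes the routine variant-filtering front end that produces
    the candidate gene set from an annotated variant table, and a spike-in
    simulation benchmark with synthetic conservation matrices, ontologies and
    variant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
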