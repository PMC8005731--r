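Package: phageome
Title: Culture-Assisted Virome Analysis and Phage-Host Linking by
    Enrichment Z-Scores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of serial enrichment-culture viromes: pooling and
    dereplication of per-sample viral contigs into a representative
    database, terminal-repeat circularity detection, viral-origin
    classification from pVOG density and external evidence, k-mer
    pseudo-assignment of reads into a relative-abundance matrix, per-pool
    Z-score outlier detection with the three-step shortlist cascade that
    links strongly enriched phage genomes to bacterial host strains, and
    sample-level summaries with PCoA ordination on Spearman correlation
    distances. Includes a synthetic-data generator that emulates
    triple-round enrichment experiments with known phage-host ground
    truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Sequencing, Software
RoxygenNote: 7.3.3
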