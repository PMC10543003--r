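Package: fermprot
Title: Temporal Proteomics of Brewing Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of label-free proteomics time courses sampled across
    beer fermentation and yeast repitching. Implements spectral-count
    quantification with in-silico tryptic digestion and peptide-length
    correction (ppm abundances), replicate quality control, pairwise
    differential expression with Benjamini-Hochberg control and fold-change
    gating, trajectory clustering with dendrogram node-depth cluster
    extraction and hypergeometric term enrichment, differential pathway
    perturbation scoring (DRPS/DPPS) with entity-removal re-ranking, and
    protein-complex and subcellular-compartment co-regulation analysis.
    Ships a synthetic fermentation-proteome generator with known ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
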