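Package: paleosynteny
Title: Synteny-Based Reconstruction of a Paleohexaploid Ancestral Genome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of descendants of an ancient
    whole-genome triplication against a non-triplicated outgroup. Detects
    collinear synteny blocks from gene-order anchors, computes syntenic
    depth, clusters microsynteny networks, counts chromosomal fissions and
    fusions, reconstructs triplicated ancestral genomic blocks and a model
    ancestral genome, quantifies per-homoeolog gene retention and
    fractionation reciprocity in sliding gene windows, estimates pairwise
    synonymous substitution rates (Nei-Gojobori 1986), and identifies
    retained triplicated genes with expression tissue-specificity (tau) and
    annotation over-representation statistics. Includes a genome-evolution
    simulator (two-step triplication, biased fractionation, rearrangements,
    planted loss-immune triplets) with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
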