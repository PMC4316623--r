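Package: netcosel
Title: Network Coselection Analysis of Recent Positive Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide scan for recent positive selection in three
    populations using a composite-of-multiple-signals (CMS) score that
    combines derived allele frequency, cross-population frequency
    differences, Weir-Cockerham FST and the lnRsb long-haplotype
    statistic, followed by analysis of where the candidate genes sit on a
    protein-protein interaction network: centrality-interval enrichment,
    shortest-path-length coselection proportions with resampling nulls,
    per-gene trifurcate divergence trees with ranked-tree-distance and
    synergy (Syn) similarity statistics, and extraction of coselection
    clusters.  Includes a synthetic-data generator (drift-differentiated
    allele frequencies, founder-mosaic haplotypes with linkage
    disequilibrium, planted selective sweeps, scale-free interaction
    networks with planted coselection clusters) so that every stage can
    be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    vcfR
Suggests:
    GenomicRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
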