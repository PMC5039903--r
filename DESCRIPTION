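Package: cisScan
Title: Comparative Analysis of Regulatory-Region Alignments: GC Contrast,
    Motif Conservation and Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of aligned gene regulatory
    regions across species. Provides gap-based alignment trimming
    (gappyout-style and complete deletion), sliding-window GC content with
    Welch two-group contrasts and Bonferroni family-wise control, detection
    of contiguous significant core regions, exact-motif (e.g. E-box CACGTG)
    conservation scanning projected through the alignment, maximum-likelihood
    phylogeny under HKY85 with discrete-gamma rate variation (Felsenstein
    pruning, NNI search, nonparametric bootstrap), trait-monophyly tests,
    and a phylogenetic sequence simulator with position-dependent base
    composition, trait-linked compositional cores, planted motifs and indels
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
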