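Package: snippetr
Title: Mini-Barcode 'Snippet' Discovery and Haplotype Phylogeography for
    Degraded Mitochondrial DNA
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Locates short, hyper-variable, primer-flankable windows
    ("snippets") in mitochondrial control-region alignments so that highly
    degraded skeletal material can be typed from very short amplicons.
    Provides parsimony-based per-site change profiling on neighbour-joining
    trees with binned mutation-rate calibration, exact-string haplotype
    assignment for short fragments, gap-aware minimum spanning haplotype
    networks with equal-cost alternative links, locality grouping and
    phylogeographic diversity ratios, an avian W-chromosome molecular-sexing
    decision procedure, and a coalescent simulator of control-region
    alignments with a planted mutational hotspot and ancient-DNA
    fragmentation for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
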