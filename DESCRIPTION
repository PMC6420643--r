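Package: deamtrace
Title: Lineage Tracing with a Targeted Cytidine-Deaminase Barcoding System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cell-lineage tracing with a nickase-Cas9 cytidine deaminase
    (base editor) that writes C-to-T substitution barcodes into endogenous
    interspersed repeat targets. Covers the full computational workflow: screening
    sequences for deaminase-targetable protospacers and ranking multi-copy spacers;
    UMI-based molecule counting with Hamming-distance clustering; calling edits from
    pileup counts with a binomial-mixture EM model plus confidence and site-selection
    filters; bulk lineage-tree reconstruction by overlap-based clade detection and
    iterative Poisson-binomial top-node selection; single-cell tree reconstruction by
    Jaccard-distance average-linkage clustering with bootstrap support; exponential
    fitting of editing-rate dynamics; and a barcode-accumulation simulator that
    predicts reconstruction accuracy under editing rate, target dropout, and
    site-editing bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    vegan,
    minpack.lm,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
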