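Package: triadtrack
Title: Homoeolog Histone-Modification and Expression Bias Tracking in
    Polyploid Wheat
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Triad-wise quantification and classification of subgenome bias
    in allopolyploid wheat chromatin and expression data.  Gene-level read
    counts for histone-mark ChIP (H3K4me3, H3K27me3) and RNA assays are
    converted to TPM, each homoeolog triad is normalized to relative A/B
    signal, and triads are classified as balanced (A=B) or biased (A>B,
    A<B) by nearest Euclidean anchor.  Per-triad categories are tracked
    across three-genotype series (wild -> domesticated -> extracted
    tetraploid; hexaploid -> extracted tetraploid -> resynthesized
    hexaploid) into four transition groups, with the accompanying
    statistics: exact binomial subgenome-asymmetry test, two-sample
    proportion tests, Wilcoxon rank-sum comparisons of modification level,
    hypergeometric GO enrichment with Benjamini-Hochberg FDR, chromosomal
    zone distributions, and modification-expression concordance.  A
    synthetic-data generator with planted ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
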