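Package: PhyloCongruence
Title: Congruence, Saturation and Rogue-Taxon Diagnostics for Tree Samples and Multigene Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Split-based diagnostics for Bayesian (or bootstrap) tree samples and
    the multigene nucleotide alignments behind them. Computes bipartition split
    frequencies, the average standard deviation of split frequencies (ASDSF)
    between tree samples, majority-rule consensus trees with support and
    resolution percentages, and greedy rogue-taxon dropset searches that
    maximise consensus support. Alignment-level statistics cover site
    classification (variable and parsimony-informative sites), base composition
    and GC content, a chi-square test of base-compositional stationarity across
    taxa, and uncorrected p-distances for saturation plots against patristic
    distances. Also extracts alignment anchor constraints from conserved stem
    regions, censuses taxon-by-gene presence matrices, and ships a GTR+G+I
    sequence simulator (with optional lineage-specific GC drift) plus
    pseudo-posterior tree-sample generators so every stage can be exercised on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape (>= 5.0),
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
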