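Package: oxyGC
Title: Phylogenetically Controlled Analysis of GC Content and Oxygen
    Requirement in Prokaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether aerobiosis is associated with genomic
    GC content while controlling for shared ancestry. Computes GC content of
    whole sequences and of codon-degeneracy site classes (fourfold degenerate
    third positions, zerofold redundant second positions) from coding
    sequences; builds neighbour-joining trees from p-distances with bootstrap
    support; extracts phylogenetically independent aerobe-anaerobe pairs from
    a labelled phylogeny; fits phylogenetic generalized least squares (PGLS)
    regressions of GC content on ordinal oxygen-requirement codes under a
    Brownian-motion covariance with Pagel's lambda; and provides exact and
    asymptotic Wilcoxon signed-rank and Mann-Whitney U tests. A synthetic-data
    module generates Yule trees, oxygen-state histories with a controlled
    number of transitions, Brownian GC-like traits, coding sequences with
    prescribed site-class GC, and aligned 16S-like sequence pairs with known
    identity, so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
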