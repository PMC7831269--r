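Package: entroTAD
Title: Hierarchical TAD Detection from Hi-C Contact Maps by Structural
    Entropy Minimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hierarchies of topologically associating domains (TADs)
    from Hi-C contact matrices by finding coding trees of minimal structural
    entropy with exact dynamic programming. Provides an unconstrained mode
    that selects the number of leaf domains automatically, a height-bounded
    mode for trees of at most a given depth, density-based filtering of
    non-TAD nodes, partition-similarity metrics (overlapping ratio, weighted
    similarity, measure of concordance), readers and writers for plain-text
    contact matrices and domain calls, and a planted-block simulator for
    benchmarking recovery under noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
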