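Package: lpfs
Title: Semi-Supervised Feature Selection by Label Propagation on Sample
    Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint sample clustering and gene selection for multi-class
    transcriptomic designs. Alternates graph-based label propagation over
    a Gaussian-kernel sample-similarity network with l2,1-regularised
    non-negative feature selection on the expression matrix, iteratively
    eliminating uninformative genes by rank product and reporting
    consensus per-category key-gene sets across randomised restarts.
    Includes multi-label ranking metrics (Hamming loss, one-error,
    coverage, AUC, AUPR), fold-change and Welch t-test baseline scorers,
    and a synthetic-data generator with planted per-category markers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
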