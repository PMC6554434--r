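Package: assemblyseq
Title: Unsupervised Detection of Repeated Cell-Assembly Spike Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects groups of neurons that repeatedly fire in fixed temporal
    patterns ("cell assemblies") from parallel spike-train recordings, without
    reference events. Population activity is segmented into binned time
    windows, pairwise window similarity is scored with an extended
    Needleman-Wunsch edit similarity (inner-product matching, exponential gap
    penalty, local restart), candidate pairs are pruned with MinHash
    locality-sensitive hashing on active-neuron sets, windows are grouped by
    density-based noise removal (OPTICS) followed by overlapping community
    detection (COPRA), and each cluster's consensus spatiotemporal pattern is
    constructed by iterative profile alignment. Includes Poisson spike-train
    simulators with embedded synchronous and sequential assemblies,
    supervised and unsupervised clustering scores, and a Bayesian
    smooth-baseline jump model for position-resolved significance of profile
    matches against rate-preserving surrogates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    rjags,
    coda,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    vegan
Config/testthat/edition: 3
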