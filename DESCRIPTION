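Package: iterotu
Title: Iterative Subsample-and-Recruit OTU Clustering for Amplicon Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative sampling-based clustering of deduplicated amplicon
    (e.g. 16S rRNA gene) sequences into operational taxonomic units. In each
    iteration a small uniform subsample of the unclustered pool is clustered
    greedily at a fixed similarity radius; representatives of non-singleton
    subsample clusters are then used as baits to recruit the remaining
    sequences, representatives are mode-shifted to the highest-multiplicity
    member, and the sampling rate adapts as iteration productivity drops.
    Includes the exact and bounded hypergeometric probabilities of detecting
    or missing clusters under uniform subsampling, a coin-flip iteration
    simulator, a bootstrap upper bound on undetected cluster sizes, cluster
    fragmentation and entropy diagnostics, and a synthetic amplicon community
    generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
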