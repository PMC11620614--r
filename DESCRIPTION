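Package: seqspace
Title: Percolation Analysis of Continuous Functional Paths in Protein Sequence Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the connectivity of functional protein
    sequences in discrete sequence space through the lens of site
    percolation. Provides closed-form percolation thresholds for
    substitution neighbourhoods of one or more mutations, the biasing
    ratio comparing the threshold to a protein's proportion of functional
    sequences, hyper-exponential models of local functionality decay with
    Hamming distance from a wildtype (including fitting and the maximum
    distance at which extensive continuous functional paths can exist),
    and a deterministic Monte-Carlo simulator of site percolation on
    L-position, A-letter sequence spaces with cluster search, target
    connectivity, phase-transition sweeps and cluster-size power-law
    fitting. Bundled fixtures reproduce published threshold tables for
    sixteen peptides and proteins and local-functionality parameters for
    beta-lactamase, GFP and HisA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
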