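Package: nucpot
Title: Inter-Nucleosomal Pair Potentials from Nucleosome Positioning Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts effective inter-nucleosomal pair potentials from
    genome-wide nucleosome positioning tracks. Chromosomes are partitioned
    into overlapping sections; for each section the one-dimensional radial
    distribution function of nucleosome centers is computed and a generalized
    Lennard-Jones potential is fitted by reverse Monte Carlo, with a
    tournament-style noisy optimizer (intuitive selection strategy) replacing
    the usual Markov-chain outer loop. From the fitted potentials, reduced
    isothermal compressibilities are estimated by the block density
    distribution method with finite-size extrapolation, and sections are
    classified into chromatin-like states by k-means clustering on the
    potential exponents and compressibility. Includes synthetic-data
    generators (Poisson, Tonks hard-rod, and known-potential tracks) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    lhs,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
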