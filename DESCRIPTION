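Package: redpart
Title: Redundancy-Based Coordination Measures and Partitioning for Collective Systems
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies coordination in multivariate systems (fish schools,
    flocks, neural populations) by relative redundancy: total correlation
    normalized by the summed marginal entropies, a dimensionless measure
    comparable across systems of any size. Provides exact discrete
    computation, a practical Gaussian-copula lower bound for continuous data
    (rank-Gaussianization plus a fixed quantization offset), and an
    alternating-minimization algorithm that partitions a system into its most
    coordinated components, with exact, Monte-Carlo and hard-partition
    variants and a delta-average-redundancy scan for choosing the number of
    components. Includes seeded Vicsek and attraction-alignment-repulsion
    schooling simulators and a trajectory-analysis pipeline (Savitzky-Golay
    velocity estimation, time windowing).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
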