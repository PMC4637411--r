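Package: PottsNet
Title: Inverse Potts Network Reconstruction from Affiliation Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs pairwise interaction networks among agents from
    repeated observations of their discrete Q states, using the inverse
    Q-state Potts model solved in the moment representation of loopy belief
    propagation under the Bethe approximation. Couplings are expanded in
    discrete orthonormal (Gram/Chebyshev) polynomials and inverted in closed
    form from smoothed pairwise marginals. Includes the observation-building
    strategies for binary affiliation (two-mode) data -- generative,
    semi-observational and pure observational -- co-occurrence alpha
    weighting schemes, a heat-bath Gibbs sampler, standard one-mode
    projection baselines (Jaccard and siblings), greedy modularity (CNM)
    community detection with forced merging, misclassification (FDR)
    evaluation, threshold sweeps, and seeded synthetic-data generators with
    planted group structure for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
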