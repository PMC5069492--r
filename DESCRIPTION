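Package: glycotraj
Title: Conformational Trajectory Analysis of Branched N-Glycans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational dynamics of bi- and
    tri-antennary N-glycan chains from coarse-grained trajectories.
    Builds block-level glycan topologies with explicit glycosidic phi/psi/omega
    dihedral definitions, generates synthetic trajectories from per-linkage
    angular mixture models with Markov state switching, and provides the
    downstream analyses: GROMOS conformer clustering with automatic cutoff
    selection, conformational-state labelling and transition counting,
    block-averaged RMSF with Welch comparison, inter-block contact and
    difference maps, circular modal decomposition of glycosidic dihedral
    distributions, and the "umbrella" projection of antenna positions onto an
    oriented plane with spot occupancy and distance-dihedral rank correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
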