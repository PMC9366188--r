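Package: coalclock
Title: Multispecies Coalescent Inference and Simulation under Relaxed Molecular Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian MCMC inference under the multispecies
    coalescent (MSC) with relaxed molecular clocks. Gene-tree densities under
    the MSC, per-locus substitution-rate priors (conditional i.i.d. and
    gamma-Dirichlet), independent- and correlated-rates models of rate
    evolution along species-tree branches with gamma or log-normal kernels,
    GTR+Gamma pruning likelihoods, Metropolis-Hastings sampling of species
    divergence times, population sizes and rate parameters on a fixed species
    tree, NNI-based species-tree search for small trees, a coalescent
    simulator of multilocus alignments, and the prior-sampling and
    Bayesian-simulation harnesses used to validate the samplers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
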