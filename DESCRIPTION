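Package: guanotype
Title: Non-Invasive Microsatellite Genotyping, Hybrid Classification and
    Colony-Size Estimation from Guano
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for non-invasive genetic studies of mixed-species bat
    colonies sampled through guano. Implements replicate-PCR consensus
    genotyping with the multiple-tubes rule, near-identity matching of
    samples into individuals, a six-class Bayesian genotype-frequency
    mixture (purebreds, F1, F2 and backcrosses) fitted by Gibbs sampling
    with threshold assignment criteria, simulation-based evaluation of
    hybrid-detection performance (efficiency, accuracy, type-I error),
    population-genetic summaries (allele-frequency differentials, rarefied
    allelic richness, Hardy-Weinberg and linkage exact tests, G-tests,
    Weir-Cockerham F_ST), and genotype-based colony-size estimators
    (accumulation-curve asymptote and sequential Bayesian). A synthetic-data
    generator reproduces the sampling structure of a mixed maternity colony
    (replicated PCRs, allelic dropout, false alleles, repeated captures).
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
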