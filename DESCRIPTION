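Package: wgdcompass
Title: Detection and Phylogenetic Placement of Ancient Whole-Genome
    Duplications from Ks Distributions and Bayesian Reconciliation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated workflow for detecting ancient whole-genome
    duplications (WGDs) from synonymous-distance (Ks) age distributions and for
    placing and statistically testing WGD hypotheses on a species phylogeny.
    Provides an NG86 pairwise Ks engine with node-weighted paranome and
    one-to-one ortholog distributions, log-scale Gaussian and
    exponential-lognormal mixture modelling with BIC selection, SiZer kernel
    significance maps for peak validation, two substitution-rate correction
    schemes (halved-peak placement on a Ks-unit phylogram and trio-based
    relative-rate correction with multi-outgroup consensus), Bayesian gene
    tree - species tree reconciliation under duplication-loss models with WGD
    retention (amalgamated conditional-clade likelihood, adaptive MCMC,
    Savage-Dickey Bayes factors), synteny-anchor filtering, and a forward
    simulator of gene family evolution so that every stage is testable on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    phangorn,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
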