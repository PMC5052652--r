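Package: ornamass
Title: Phylogenetic Comparative Analysis of Cranial Ornamentation and
    Body-Mass Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing correlated evolution between a binary
    cranial-ornamentation character and continuous (log) body mass on
    time-scaled fossil phylogenies. Provides fossil-tree time-scaling
    (ABA, MBL, Equal), phylogenetic generalized least squares with Pagel
    lambda/kappa/delta branch-length transforms (maximum likelihood and
    MCMC over tree sets), Felsenstein's threshold model for
    discrete-continuous correlation, continuous-time Markov (Mk)
    inference for binary characters including reversible-jump MCMC over
    rate models, ancestral-node "fossilization" Bayes-factor tests and
    stochastic character mapping, multi-regime Ornstein-Uhlenbeck
    (generalized Hansen) model fitting on regime-painted trees with
    information-theoretic model averaging, and seeded synthetic-data
    generators (birth-death trees with extinct tips, Mk histories,
    regime-dependent OU traits) so that every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    phytools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
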