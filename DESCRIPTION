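Package: phenoclade
Title: Phylogeny-Aware Benchmarking of Microbial Trait Prediction from Gene Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating statistical prediction of binary microbial
    phenotypes (e.g. growth on single carbon sources) from gene
    presence/absence profiles. Implements random and out-of-clade
    train/test partitioning on a phylogeny, nearest-neighbor, random-forest
    and L1-regularized logistic-regression classifiers, Bernoulli and
    majority-class null models with a permutation-test significance
    protocol, phylogeny-trait correlation-length estimation, a
    nearest-neighbor mimicry diagnostic, feature selection by conditional
    entropy, meta-learning and reaction-graph queries, and a simulator of
    phylogenetically structured genotypes with boolean logic traits for
    benchmarking at controlled sample sizes and trait complexities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    ranger,
    glmnet,
    rpart,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
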