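Package: syntnet
Title: Syntactic Dependency Networks of Learner Corpora
Version: 0.1.0
Authors@R: person("syntnet", "maintainers", email = "syntnet@example.org",
    role = c("aut", "cre"))
Description: Builds undirected word-type syntactic networks from
    dependency-annotated corpora (CoNLL-U or a compact tabular dialect),
    computes the standard complex-network panel (average degree, clustering
    coefficient, average path length, density, degree centralization),
    fits power-law and Poisson models to cumulative degree distributions,
    assesses small-world and scale-free status against matched G(N,M)
    random baselines, and runs cross-proficiency regression and
    cross-modality t-test batteries over a table of per-corpus metrics.
    Includes a seeded synthetic treebank generator (Zipfian lexicon,
    hub-biased random recursive trees) so the full pipeline is testable
    without access to learner corpora, plus a scriptable command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
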