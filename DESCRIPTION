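Package: dupisodes
Title: Minimum Duplication Episodes from Rooted and Unrooted Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genomic duplication episodes (including whole-genome
    duplication candidates) by reconciling collections of rooted and unrooted
    gene family trees with a fixed rooted binary species tree. Implements
    duplication-cost reconciliation via the least-common-ancestor mapping,
    plateau-based unrooted reconciliation with edge typing and optimal-rooting
    analysis, the equivalence-class decomposition of an unrooted gene tree,
    exact and linear-time bounding solvers for the minimum-episodes score, a
    quadratic heuristic for large inputs, episode reconstruction with
    species-tree locations, a duplication-loss-speciation (DLS) scenario
    grammar, and a seeded duplication-loss simulator for generating synthetic
    gene families with injected multi-family duplication episodes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
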