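Package: phenoattract
Title: Phenotype-Constrained Attractor Search for Synchronous Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds all attractors of a synchronous Boolean network that realise
    a phenotype of interest, without enumerating the full state space. Clamped
    environment values and the required phenotype marker values are propagated
    through the update rules by partial evaluation; the residual network is
    decomposed into strongly connected components arranged in a hierarchical
    partition; local attractors of each component, driven by the periodic
    signal of upstream components, are found by exhaustive search and
    concatenated (subject to residual constraint equations and inequalities)
    into verified global attractors of the original network. Supports logic
    update rules and threshold (sign) rules, a plain-text rule format in the
    'targets, factors' convention, a brute-force full-search oracle for
    validation, and generators of random and structured synthetic networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
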