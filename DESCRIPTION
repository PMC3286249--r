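Package: moriomorph
Title: Maximum Parsimony Analysis of Morphological Character Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cladistic analysis of discrete morphological data
    under the maximum parsimony criterion: NEXUS and TNT-style matrix
    input/output with polymorphic and missing cells, mixed additive
    (ordered) and nonadditive (unordered) character costs via generalized
    Sankoff dynamic programming, heuristic tree search by random stepwise
    addition with SPR/TBR branch swapping and the parsimony ratchet, exact
    branch-and-bound for small taxon sets, ensemble consistency and
    retention indices, and ACCTRAN/DELTRAN apomorphy mapping onto edges.
    Ships the 22-taxon by 75-character matrix for the carabid beetle tribe
    Moriomorphini (Trechus obtusus outgroup) and a one-call reproduction
    of its published analysis, together with a simulator for discrete
    character evolution on known trees used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
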