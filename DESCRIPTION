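Package: maxpars
Title: Maximum Parsimony Analysis of Discrete Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cladistic analysis of discrete morphological data:
    reading, writing and recoding NEXUS and TNT character matrices with
    missing, inapplicable and polymorphic cells; Fitch (unordered) and
    Wagner (ordered) parsimony tree lengths; exhaustive, branch-and-bound
    and random-addition + tree-bisection-reconnection tree searches;
    strict and majority-rule consensus; Bremer decay and nonparametric
    character bootstrap supports; ACCTRAN/DELTRAN ancestral states and
    synapomorphy mapping with per-character consistency indices; and a
    seeded simulator of morphological matrices with known true trees,
    including a tooth-only-taxon degradation mode, so every stage of the
    workflow can be exercised without external data. Motivated by the
    reanalysis workflow used to place the Eocene eagle ray Promyliobatis
    gazolai among the pelagic stingrays (30 taxa, 103 characters).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
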