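Package: poehs
Title: Parent-of-Origin Effects in Heterogeneous Stock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and quantification of parent-of-origin effects in
    multiparental outbred populations such as the mouse heterogeneous stock.
    Provides a pedigree-aware hidden Markov model that infers phased founder
    diplotype probabilities from offspring and parental genotypes, a
    decomposition of marker-based kinship into same-parental-sex (K+) and
    opposite-parental-sex (K-) components, two-component REML estimation of
    the corresponding heritabilities, a mixed-model imprinted-QTL scan whose
    false discovery rate is calibrated against simulated non-imprinted
    complex traits, and nested-model analyses of reciprocal F1 crosses.
    Includes a forward-in-time simulator of pedigreed founder-mosaic
    populations so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
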