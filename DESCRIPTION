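Package: scorpallo
Title: Phylogenetic Comparative Analysis of Reproductive Allocation in
    Scorpions
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of male reproductive allocation (testes
    mass, spermatophore volume, sperm length) against body mass and
    polyandry level across bothriurid scorpions.  Implements generalized
    least-squares regression under a Pagel's-lambda phylogenetic
    covariance with maximum-likelihood lambda estimation, likelihood-ratio
    tests of phylogenetic signal, sequential (Type I) ANOVA, AICc-based
    multimodel selection with Akaike weights, descriptive allometry and
    gonadosomatic-index summaries, and simulators for both species-level
    traits evolving on a tree and the individual-level sampling design of
    a comparative dissection study.  Ships the eight-species trait table
    and default cladogram used throughout as plain-text fixtures.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
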