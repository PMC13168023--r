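Package: coabnet
Title: Longitudinal Microbial Co-Abundance Networks, Guilds, and Metabolic
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Compositionality-aware inference of microbial co-abundance
    networks (SparCC with permutation pseudo p-values and FDR filtering),
    cross-age classification of edge conservation and heterogeneity via
    fixed-effect Fisher-z meta-analysis (Cochran's Q, I-squared), network
    topology (modules, Zi-Pi node roles, degree-distribution fits),
    resilience analysis (abundance-weighted mean interaction strength,
    stability, efficiency-based vulnerability, targeted-versus-random
    removal robustness), detection of antagonistic phenotype-associated
    guilds from signed co-abundance graphs, and scoring of metabolic
    competition and complementarity between guild members. Includes a
    synthetic-data generator with planted ground truth so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
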