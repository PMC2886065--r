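Package: lascout
Title: Liquid Association Scouting for Mediators of Gene Coexpression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for three-way coexpression (liquid association, LA)
    analysis of batched gene expression data. Expression profiles are
    Gaussianized by a per-batch normal-score transform, the LA statistic
    LA(X,Y|Z) = mean(X*Y*Z) is computed over complete sample triples, and
    genome-wide searches rank candidate mediator ("scouting") genes for
    lead gene pairs, single lead genes, and lead gene sets. Significance
    is assessed by seeded permutation tests, a large-sample normal
    approximation, and a random-pair null-pool experiment. LAP
    (liquid-association pair) views split samples by mediator level and
    contrast subgroup correlations. A synthetic-data generator with
    planted, analytically tractable mediation structure supports testing
    and calibration without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
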