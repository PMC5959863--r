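Package: repeat2shape
Title: RUNX2 Glutamine/Alanine Repeat Ratios and Craniofacial Shape Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of RUNX2 glutamine/alanine (Q/A) tandem-repeat
    ratios and palate shape across phyllostomid bats and primates. Extracts the
    Q/A repeat domain from protein or coding sequences between conserved flanking
    anchors, size-corrects linear craniofacial measurements by the specimen
    geometric mean, and relates repeat ratios to shape with tie-corrected
    Spearman rank correlations (exact permutation p-values at small n),
    phylogenetic generalized least squares with maximum-likelihood estimation of
    Pagel's lambda, and a Bayesian bivariate Brownian-motion model of correlated
    trait evolution sampled by MCMC on a fixed dated tree. Also computes
    morphological-integration indices (eigenvalue coefficient of variation,
    random-skewers evolutionary flexibility and constraints) from phenotypic
    covariance or correlation matrices, and ships simulators (Yule trees,
    bivariate Brownian traits, structured specimen samples, repeat-bearing
    sequences) that provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    coda,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
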