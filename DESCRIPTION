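Package: vestimorph
Title: Phylogenetically Informed Shape Analysis of the Primate Vestibular
    Apparatus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Group-structured ordination and phylogenetic comparative
    analysis of 3D shape descriptors, built around the statistical
    pipeline used to study semicircular-canal shape evolution in
    anthropoid primates. Provides generalized Procrustes superimposition,
    between-group principal components analysis with a-posteriori fossil
    projection, cross-validated classification and Mahalanobis typicality
    probabilities, phylogenetic-signal statistics (Pagel's lambda,
    Blomberg's K and its multivariate generalization with permutation
    tests), ordinary and phylogenetic generalized least-squares
    allometric regression with ANCOVA grade-shift tests,
    maximum-likelihood ancestral-state reconstruction with
    phylomorphospace construction, and a synthetic-data generator with
    known ground truth for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    nlme,
    vegan,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
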