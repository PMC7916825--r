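Package: mplage
Title: Metabolite Set Activity Scoring by Matrix Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks metabolite sets (metabolic pathways, molecular families,
    Mass2Motifs or any user-defined grouping of LC-MS features) by how strongly
    their activity changes between two experimental conditions. The core method,
    mPLAGE, summarises each set's feature-intensity submatrix by the first right
    singular vector of its singular value decomposition (per-sample activity
    level scores), compares conditions with a two-sample t-statistic, and
    calibrates significance against a sample-label permutation null whose
    per-round extreme t-statistics are modelled with a maximum-likelihood-fitted
    generalised extreme value distribution. Reference overrepresentation
    analysis (hypergeometric) and gene set enrichment analysis (weighted
    running-sum, sample-label permutation) implementations share the same data
    model, together with a synthetic benchmark generator (planted changing
    pathways, decoy features, random feature dropout) and precision/recall/F1
    evaluation utilities for comparing the three methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    ggplot2,
    withr
Config/testthat/edition: 3
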