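Package: somsar
Title: Supervised Self-Organizing Map Classifiers for Structure-Activity Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-activity and target-selectivity classification of small
    molecules from precomputed molecular descriptor tables. Implements
    counter-propagation artificial neural networks (CPANN) and supervised
    Kohonen networks (SKN) on square toroidal maps, partial least squares
    variable importance in projection (VIP) descriptor selection with a
    model-size sweep, descriptor preprocessing (correlation filtering and
    autoscaling), tenfold venetian-blinds cross-validation, y-randomization,
    leverage-based applicability domain assessment, and spike-in virtual
    screening with enrichment factors and ROC analysis. Includes a synthetic
    descriptor-table generator for fully reproducible pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pROC,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
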