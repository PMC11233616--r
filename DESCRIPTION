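Package: aneumorph
Type: Package
Title: Morphometric Analysis and Rupture Classification of Intracranial
    Aneurysm Surface Meshes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a battery of 35 morphological parameters from
    triangulated surface meshes of intracranial aneurysm sacs, including
    convex-hull shape indices (ellipticity, nonsphericity, undulation),
    neck-plane and ostium metrics, and isoperimetric roundness and
    sphericity scores.  Provides parametric generators for synthetic sac
    geometries with closed-form ground truth and for labelled synthetic
    cohorts, plus a rupture-status classification protocol: feature
    standardization, five classifier families tuned by grid search under
    stratified five-fold cross-validation, accuracy/precision/recall and
    ROC-AUC evaluation, and signed feature-importance attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    e1071,
    class,
    randomForest,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
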