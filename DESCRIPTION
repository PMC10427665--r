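Package: neobrainage
Title: Interpretable Neonatal Brain Age Estimation from Label-Map Morphometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates postmenstrual age (PMA) at scan for neonatal brain MRI
    from segmentation label maps alone. Extracts two per-region morphometric
    features from 3D integer label volumes -- relational volume (RV, a region's
    voxel fraction of all segmented structures) and surface-to-volume ratio
    (SVR, a gyrification proxy counting surface voxels) -- selects the most
    age-correlated features, fits a Bayesian ridge regression of PMA, and ranks
    regions by permutation feature importance. Includes a minimal NIfTI-1
    reader/writer for label volumes, cohort splitting utilities, evaluation
    metrics (MAE, squared-Pearson R2, Dice), and synthetic phantom and tabular
    cohort generators so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
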