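Package: segstruct
Title: Segmentation-Based Profile Features for Protein Structural Class
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts segmentation-based descriptors from protein
    evolutionary profiles (PSI-BLAST position-specific scoring matrices)
    and predicted secondary-structure probability profiles, and predicts
    the four SCOP structural classes (all-alpha, all-beta, alpha/beta,
    alpha+beta) with a support vector machine using a radial basis
    function kernel.  Feature groups are consensus-sequence occurrence,
    semi-composition (per-column probability sums), segmented
    distribution (cumulative-mass breakpoints from both sequence ends),
    and segmented auto covariance (lagged auto covariance over nested
    cumulative-mass segments plus the whole column).  Includes parsers
    for PSI-BLAST ASCII PSSM files and per-residue secondary-structure
    tables, stratified k-fold and jackknife cross-validation with
    per-class sensitivity, specificity and Matthews correlation, and a
    synthetic profile generator with class-dependent statistics for
    end-to-end testing without external profile generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
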