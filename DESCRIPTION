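Package: segnoninfer
Title: Non-Inferiority Evaluation of 3D Segmentation Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Agreement metrics for co-registered 3D binary segmentation
    masks on anisotropic voxel grids (volumetric similarity, absolute
    volume difference, Dice, precision, recall, 95th-percentile Hausdorff
    distance, surface Dice at tolerance) together with a margin-based
    non-inferiority framework that tests whether model-to-expert agreement
    is no worse than inter-expert agreement: one-sided Wilcoxon signed-rank
    or paired t tests gated by a Shapiro normality check, Holm-Bonferroni
    multiplicity correction, and bootstrap confidence intervals for
    medians. Includes a synthetic multi-rater lesion cohort generator so
    every stage is testable without clinical data, NIfTI mask input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    jsonlite,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
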