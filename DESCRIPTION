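Package: hpmfm
Title: Multiparametric Features of Metabolism from Hyperpolarized 13C-Pyruvate MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive and evaluate multiparametric features of
    metabolism (MFM) from dynamic hyperpolarized [1-13C]pyruvate MRI.
    Includes a synthetic cohort generator built on a discrete two-site
    pyruvate-to-lactate exchange model, voxelwise inputless kPL fitting,
    pyruvate AUC and mean pyruvate time maps, resampling to an isotropic
    analysis grid, fixed-bin-width gray-level texture features (GLDM,
    GLRLM, GLSZM) with first-order and shape descriptors, Cox
    proportional-hazards survival analysis with Harrell's concordance
    index, and a multivariate Metabolic Prognostic Score (MPS) built by
    concordance-ranked, correlation-clustered feature selection with
    leave-one-out coefficient stability assessment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
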