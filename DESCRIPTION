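Package: lungprm
Title: Parametric Response Mapping of Lung CT and Inspiratory-Only PRM
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Voxel-level parametric response mapping (PRM) of paired
    inspiratory/expiratory chest CT for quantifying air trapping:
    classification of lung voxels into normal parenchyma, functional
    small airway disease (fSAD) and emphysema by joint attenuation
    thresholds, scalar air-trapping indices (LAA-856, E/I), multi-
    resolution B-spline free-form deformation registration, and a
    cascaded generative model that synthesizes expiratory CT from
    inspiratory CT so that PRM can be predicted from a single
    inspiratory scan.  Includes a synthetic paired-CT lung phantom
    generator with known labels and deformation, image-quality and
    segmentation-agreement metrics (SSIM, RMSE, Dice), and ROC-based
    small-airway-disease stratification from PRM fSAD volume fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    grDevices,
    igraph,
    jsonlite,
    pROC,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
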