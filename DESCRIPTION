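Package: hemispec
Title: Hemispheric Specialization Mapping with Cross-Hemisphere Generative Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a 3D context-encoder generative adversarial network to
    predict one brain hemisphere's gray-matter density map from the other and
    derives voxelwise hemispheric-specialization metrics (absolute and
    relative neuroanatomical specificity, ANS/RNS) from the prediction
    residual. Includes a synthetic paired-hemisphere cohort generator with
    planted homologous and hemisphere-specific components, classical
    asymmetry-index and occlusion-saliency baselines, ComBat batch
    harmonization of specialization maps, similarity fingerprinting,
    representational similarity analysis, a multivariate variance-component
    model, spatial-autocorrelation analysis, and Jacobian-determinant
    morphometry of displacement fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    sva,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
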