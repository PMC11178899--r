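Package: morphgrad
Title: Morphological Gradients for 3D Surface-Mesh Saliency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Perturbation-based feature-importance maps for triangle meshes
    under an arbitrary scoring function. A local bump or dent is applied along
    vertex normals with a linear radial falloff, the change in the score is
    recorded, and a sparse vertex point cover with geodesic-distance
    interpolation keeps the number of score evaluations small. Includes STL
    and colored-PLY mesh input/output, mesh connectivity and graph-geodesic
    utilities, mesh-space data augmentation (bounded random rotation, shift,
    and mirroring), conservative surface voxelization with solid fill,
    a parameterized synthetic skull-proxy generator with an analytic scoring
    function for ground-truth validation, and stratified k-fold
    cross-validation with AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
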