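Package: dtiConnectome
Title: Structural Connectome Analysis of Diffusion Tensor Imaging Data
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for graph-theoretical analysis of white-matter
    structural connectivity from diffusion MRI. Covers log-linear diffusion
    tensor fitting with FA/MD/AD/RD scalar maps and head-motion quality
    control, deterministic streamline tractography with FA and curvature
    termination rules, construction of region-of-interest connectivity
    matrices weighted by streamline counts and mean axial diffusivity,
    proportional thresholding with binarized graph metrics normalized
    against degree-preserving null networks, permutation-based group
    comparison with nuisance covariates, and FDR-corrected regression of
    graph metrics on clinical scores. A synthetic-data module generates
    diffusion phantoms with known tensors and two-group connectome cohorts
    with planted effects so the full pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
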