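Package: vctdbt
Title: Virtual Clinical Trials for Digital Breast Tomosynthesis Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation toolkit for virtual clinical trials (VCTs) of digital
    breast tomosynthesis (DBT). Generates voxelized compressed-breast
    phantoms (air/adipose/dense) with a curved breast outline matched to a
    screening-population distribution, simulates cone-beam acquisition under
    conventional, T-shaped, and extra-wide-range scanning geometries with a
    Siddon ray-traced projector, reconstructs by unfiltered simple
    backprojection, segments tissue and the three-dimensional breast outline
    with a compact 3D U-Net trained on a combined focal Tversky loss, and
    evaluates segmentations with slice-distance-binned overlap metrics and
    non-parametric model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
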