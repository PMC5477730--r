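Package: ctvdelta
Title: Geometric and Dosimetric Comparison of Paired Radiotherapy Target Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing paired target-volume delineations in
    radiotherapy planning, such as structures contoured on soft-tissue versus
    lung CT window presets around air cavities. Computes volumes, surface
    areas and symmetric 3D/2D Hausdorff distances between triangular surface
    meshes; builds clinical target volumes by isotropic margin expansion with
    anatomical-barrier cropping on voxel grids (exact anisotropic Euclidean
    distance transform); extracts dose-volume-histogram metrics (Dx%, hot
    spot) from dose grids; classifies plans against three-level protocol
    objectives; and generates seeded synthetic phantoms (C-shaped targets
    wrapping a cylindrical air cavity with conformal penumbra dose) for
    end-to-end validation. Reads and writes STL, PLY and NRRD.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
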