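Package: voxmorph
Title: Quantitative 3D Image Analysis of Porous and Multiphase Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Filtering, segmentation, mathematical morphology and quantitative
    analysis of 3D micro-CT volumes of porous and multiphase materials.
    Provides a 3D median filter, automatic Otsu thresholding, one-dimensional
    k-means gray-level clustering, binary erosion/dilation, the (3,4,5)
    chamfer distance transform, H-minima suppression, seeded morphological
    watershed, connected-component labelling, per-blob shape descriptors,
    Minkowski functionals (volume density, specific surface, integral of mean
    curvature, Euler characteristic), mean-intercept-length fabric anisotropy,
    topology-preserving skeletonisation with branch classification and
    connectivity density, trabecular bone morphometry, seedable synthetic
    phantoms with analytic ground truth, and reproducible end-to-end analysis
    protocols for pore, multiphase and bone data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
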