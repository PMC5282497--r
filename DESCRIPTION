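Package: spermtopo
Title: Radial and Longitudinal Organization of Telomeres and Centromeres in
    Sperm Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the three-dimensional and two-dimensional
    topology of FISH-labelled telomeres, centromeres, nucleolar organizing
    regions and chromocenters in human sperm nuclei. Provides a synthetic
    image generator (ellipsoidal DAPI nuclei, clustered FISH spots, PSF blur,
    tail-proximal background, read noise), nucleus segmentation and signal
    detection on 3D voxel stacks, radial positioning by an exact anisotropic
    Euclidean distance transform normalized to the widest radial diameter,
    longitudinal positioning along the tail-to-head axis, single-linkage
    cluster and chromocenter colocalization counting with an exact
    combinatorial null, and chi-squared randomness statistics with both
    equal-thirds and Monte-Carlo volume-weighted nulls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
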