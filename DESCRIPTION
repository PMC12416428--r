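Package: foamvox
Title: Time-Resolved 3D Quantification of Foam-Like Cellular Materials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying time series of three-dimensional tomograms
    of liquid foams and other foam-like cellular materials. Covers the full
    chain from grayscale volumes to per-bubble measurements: background
    removal, phase segmentation, speckle removal, marker-controlled 3D
    watershed bubble segmentation and edge-bubble removal; structural
    parameters (liquid fraction, equivalent and Sauter radii, polydispersity,
    local thickness); bubble contact networks, film geometry and coordination
    numbers; per-bubble shape and texture tensors with logarithmic strain
    tensors and the interfacial (Batchelor) elastic stress tensor integrated
    over meshed bubble surfaces; centroid tracking with a volume-matching
    criterion and multi-step trajectory assembly; detection of elementary
    topological rearrangements (T1 events) from lost and newly formed
    contacts; cylindrical and spherical tensor passage and grid averaging.
    A synthetic-foam generator with exact ground truth supports end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
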