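Package: nasorecon
Title: Virtual Nasal Defect Reconstruction with a Graph-Convolutional Face Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for virtual reconstruction of full nasal defects on
    fixed-topology 3D facial meshes.  Implements a dual-branch
    graph-convolutional mesh autoencoder with spherical latent
    regularization, defect-guided construction of a personalized 3D
    target reference face by joint optimization of a latent code and a
    rigid transform against the unidirectional chamfer distance,
    boundary-projection extraction of the reconstructed nose, and
    surface/curve deviation metrics (RMSD and maximum deviation,
    localized to the nine nasal subunits).  Includes a synthetic
    structured-face generator so the whole pipeline can be exercised
    and validated without clinical scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
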