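Package: xray2bone
Title: Single-View 2D-3D Reconstruction of Distal Forearm Bones from
    Radiograph-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, end-to-end pipeline for estimating 3D bone shape
    (distal radius and ulna) from a single 2D radiograph-like image.
    Provides a reproducible synthetic wrist-phantom generator, a digitally
    reconstructed radiograph (DRR) renderer based on ray integration of
    Hounsfield-derived linear attenuation, landmark-based anatomical
    normalization into a fixed field of view, seeded 3D rigid and 2D affine
    data augmentation, intensity-based 2D-3D rigid registration with a
    gradient-correlation similarity, a paired conditional adversarial image
    translator that maps degraded radiographs to clean segmented-bone DRRs,
    a three-stage TL-embedding reconstruction network (3D label autoencoder
    plus 2D-to-latent predictor), and evaluation via mean absolute error and
    average symmetric surface distance on marching-cubes surface points.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
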