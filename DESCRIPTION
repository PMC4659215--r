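Package: rmireg
Title: Cross-Modality Registration of Hyperspectral Microscopy Images in
    Stained Tissue Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated template-matching registration of vibrational
    microspectroscopic (FTIR/CARS-style hyperspectral) region-of-interest
    images within whole-slide Hematoxylin & Eosin stained RGB images. Both
    modalities are presegmented into index-color images by k-means clustering
    with k-means++ seeding; candidate rigid or similarity transforms are
    scored with restricted mutual information, a background-aware variant of
    mutual information; and the transform space is explored with a sparse
    coarse-to-fine grid search whose initial grid radius is estimated
    automatically by self-registration of the template. Includes H&E
    preprocessing (optical-density color-cast correction, resolution
    matching, background masking), a synthetic phantom generator with known
    ground-truth transforms, file I/O for ENVI/CSV hyperspectral cubes and
    PNG images, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    Rcpp,
    EBImage,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
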