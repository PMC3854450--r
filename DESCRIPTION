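Package: imgchain
Title: Algorithm-Chain Model Selection, Classification and Annotation for
    2D/3D Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A modular toolkit for supervised classification and annotation
    of two- and three-dimensional microscopy images.  Feature extractors
    (3D anisotropic Haar wavelet textures, Hu and Zernike moment
    invariants, object statistics, Gaussian-derivative/Hessian features),
    Fisher-criterion feature selection and a set of standard classifiers
    are composed into "algorithm chains" that are compared by repeated
    stratified cross-validation to select a model.  Trained models can be
    applied to whole images, to regions of interest by sliding-window
    voxel classification restricted to grayscale local maxima, and to
    object counting via mean-shift center merging.  Includes readers and
    writers for TIFF/PNG stacks, ImageJ ROI archives and Vaa3D landmark
    files, plus deterministic synthetic-image generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    randomForest,
    rpart,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
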