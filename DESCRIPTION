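Package: celltex3d
Title: 3D Multispectral Texture Analysis of Abnormal Colorectal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying abnormal colorectal cell
    types (benign hyperplasia, intraepithelial neoplasia, carcinoma) from
    multispectral microscopy volumes using volumetric texture analysis.
    Provides active-contour (Chan-Vese) cell segmentation with overlap
    metrics, masked 2D and 3D gray-level co-occurrence matrices over the 13
    half-space directions of the 26-neighborhood, twelve Haralick texture
    statistics assembled into grouped feature vectors, ANOVA significance
    filtering with PCA reduction, and leave-one-out cross-validated decision
    tree, naive Bayes and nearest-neighbor classification. A synthetic
    phantom generator with class-dependent texture heterogeneity makes the
    whole pipeline testable without access to clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    methods,
    tiff,
    png,
    EBImage,
    rpart,
    e1071,
    pROC,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
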