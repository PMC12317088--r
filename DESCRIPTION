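Package: poolreg
Title: Feature-Based Multi-Modal Image Registration with Pyramid
    Average-Pooling Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised, parameter-free feature extraction and matching
    for registering 2D biomedical images across modalities (histology,
    mass-spectrometry imaging and similar). Dense hierarchical
    average-pooling descriptors are computed over a working window, a
    feature-magnitude map drives distance-regulated keypoint selection,
    correspondences are established by a Lowe-style ratio test on
    descriptor distances and filtered by a robust perspective-consistency
    consensus, and the final 2D affine transform is estimated by least
    squares. Includes quantile hotspot clipping and other preprocessing,
    Dice / Hausdorff / mutual-information evaluation metrics, and a
    synthetic fixture generator producing modality-shifted image pairs
    with known ground-truth transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    tibble,
    tiff,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
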