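Package: ugbnet
Title: Guided Non-Local Attention Segmentation of Spinal Ultrasound Bone Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of bony features (spinous processes,
    laminae, transverse processes, ribs) in B-mode spinal ultrasound frames
    with a guided non-local attention network: a ResNet-style encoder, dense
    atrous spatial pyramid pooling, multi-scale feature fusion, and global
    guidance blocks that refine features with spatial-wise and channel-wise
    attention steered by a multi-scale guidance map. Includes a reverse-mode
    automatic-differentiation core written in R, Adam training with k-fold
    cross-validation, Dice/Jaccard/precision/recall evaluation, dense-CRF
    mean-field post-processing, and a speckle-phantom generator that produces
    paired synthetic ultrasound images and bone masks for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
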