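Package: dermofusion
Title: Hybrid CNN-Transformer Analysis of Dermoscopic Skin Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for seven-class dermoscopic skin lesion analysis in the
    HAM10000/ISIC-2018 style. Implements a deterministic image enhancement
    pipeline (adaptive local-statistics smoothing fused with Laplacian
    sharpening), morphological hair detection with inverse-distance
    inpainting, a class-balancing augmentation planner, patch embedding
    with fixed sinusoidal positional encodings, a spatial detail
    enhancement block, a multi-head self-attention transformer encoder, a
    declarative builder for a pruned DenseNet169 backbone with exact
    parameter accounting, an element-wise feature-fusion classifier head
    with a desk-scale training harness built on a small reverse-mode
    automatic-differentiation core, confusion-matrix metrics (one-vs-rest
    precision, sensitivity, specificity, accuracy, ROC-AUC), McNemar's
    paired test, and a synthetic dermoscopy image generator used for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
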