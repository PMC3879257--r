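Package: sparsehmax
Title: Sparse-Coding HMAX Hierarchies for Visual Feature Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements sparse HMAX, a cortex-inspired hierarchical visual
    recognition model that alternates template-matching S layers, whose bases
    are learned by independent component analysis (ICA), standard sparse
    coding (SSC), L2-regularized coding, or random patch extraction, with
    spatial max-pooling C layers. Includes PCA whitening of image patches,
    layerwise unsupervised training, spatial-pyramid feature extraction,
    basis visualization by back-projection, pooling-induced correlation
    statistics, ROC/AUC unit-selectivity probes, threshold-based detector
    units, distortion-invariance curves, synthetic image generators for
    controlled experiments, and a linear-SVM classification harness with
    random-split evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
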