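Package: secbir
Title: Saliency-Enhanced Content-Based Image Retrieval for Dermoscopic Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieval-based diagnosis support for dermoscopic skin-lesion images.
    Trains a seven-class convolutional classifier on HAM10000-style image
    collections, extracts vanilla-gradient saliency maps, fine-tunes a
    four-channel (RGB + saliency) classifier, indexes pooled deep features, and
    answers ranked cosine-similarity queries with lesion-level deduplication.
    Includes a synthetic dermoscopy generator with ground-truth lesion masks,
    retrieval-precision metrics (P@k, macro AP@k), majority-vote diagnosis, and
    reader-study analytics (accuracy, Likert confidence, Cohen kappa, aggregated
    confusion matrices, melanoma over/under-diagnosis rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    withr,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
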