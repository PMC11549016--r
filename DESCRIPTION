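Package: ac4cnet
Title: Dual-Path Neural Classification of N4-Acetylcytidine Sites in mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies N4-acetylcytidine (ac4C) modification sites in mRNA
    from fixed-length sequence windows centred on a candidate cytidine. A
    dual-path neural network combines a recurrent path (integer encoding,
    learned embedding with sinusoidal positional encoding, bidirectional GRU,
    multi-head self-attention) with a convolutional path (pseudo k-tuple
    nucleotide composition features, stacked one-dimensional convolution
    blocks, multi-head self-attention); the two path summaries are
    concatenated and classified by a two-layer softmax network. The package
    provides the feature encoders, the network with hand-written
    backpropagation and Adam training, stratified k-fold cross-validation,
    the standard five-metric evaluation (sensitivity, specificity, accuracy,
    Matthews correlation, AUROC), fast-gradient-method adversarial
    perturbation for robustness assessment, an ablation harness, and a
    motif-planting synthetic benchmark generator so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
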