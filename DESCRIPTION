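Package: cdbntrack
Title: Single-Cell and Object Tracking with Convolutional Deep Belief Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Appearance-model tracking of single cells and objects in image
    sequences using a convolutional deep belief network (CDBN).  Two
    convolutional restricted Boltzmann machines with probabilistic
    max-pooling are pretrained greedily with sparsity-regularised
    contrastive divergence on a generic labelled patch set, topped by a
    fully connected head, transferred to a binary foreground/background
    head, and updated online inside a particle filter.  Drift during
    online updating is resisted by combining ground-truth, long-term
    (FIFO) and short-term positive sample buffers.  Includes OTB-style
    evaluation (precision and success plots) and deterministic synthetic
    generators for pretraining patches and cell-like tracking sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
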