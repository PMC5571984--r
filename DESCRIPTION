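Package: tdfe
Title: Tensor-Decomposition-Based Unsupervised Feature Extraction for
    Multi-View Omics Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates multiple feature-by-sample matrices (views) that
    share either their samples or their features by forming Type I
    (entry-wise product) or Type II (product summed over the shared index)
    tensors, decomposing them with higher-order singular value
    decomposition (HOSVD), and extracting features as chi-squared outliers
    on the resulting singular value vectors with Benjamini-Hochberg
    control of the false discovery rate. Includes the missing-mode
    projection that recovers per-view sample (or feature) singular value
    vectors from a Type II tensor, core-tensor ranking, association tools
    (categorical regression of singular value vectors on sample classes,
    template-profile correlations, scale-and-shift fits, UPGMA pairing of
    singular value vectors), a gram-matrix PCA baseline, and a two-view
    synthetic benchmark generator with known latent base curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
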