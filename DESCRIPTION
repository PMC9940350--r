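Package: sivae
Title: Interpretable Variational Autoencoders for Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits variational autoencoders with paired cell-wise and
    feature-wise encoder-decoders whose dot-product-coupled embeddings make
    nonlinear dimensionality reduction interpretable: cells receive scores and
    genes receive loadings, analogous to PCA. Includes Gaussian, negative
    binomial and linear observation models with optional batch correction, a
    hub-and-spoke gene co-expression network simulator, degree-centrality and
    network-neighbor analyses derived from the fitted embeddings, a
    Weisfeiler-Lehman graph-kernel workflow for comparing per-population gene
    networks against phenotypes, and k-nearest-neighbor evaluation of
    cell-embedding quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
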