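Package: richvar
Title: Richness and Variability Measures of Convolutional Filter Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes variance-based statistics of convolutional filter
    responses for computational-aesthetics research. Images are passed
    through a convolution-only filter bank (a pretrained first layer or a
    deterministic built-in Gabor / random bank), filter-response maps are
    max-pooled over n-by-n subregion grids, subregion histograms are
    L1-normalized, and three variance measures are computed per grid size:
    the total variance over all histogram entries (richness, P_a), the
    median within-subregion variance (P_g), and the median per-filter
    variance across subregions (variability, P_f). The package also
    provides a histogram-intersection self-similarity score, an RBF-kernel
    support-vector-machine protocol with stratified 5-fold cross-validation
    and exhaustive feature-subset search for art versus non-art
    discrimination, linear-SVM baselines on raw pixels and raw responses,
    and a seeded generator of synthetic image classes with controlled
    richness and variability for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    graphics,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jpeg,
    jsonlite,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
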