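Package: somamorph
Title: Soma Morphometry and Morphological Cell-Type Composition of Cerebral Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative cytoarchitectonics from two-dimensional neuron
    soma contours. Computes the ten standard soma shape descriptors
    (Perimeter, Area, Feret Max/Min, Aspect Ratio, Compactness, Convexity,
    Form Factor, Roundness, Solidity) from closed polygon outlines,
    classifies cells into eight morphological types either by explicit
    ROC-derived threshold rules or by a certainty-filtered multi-layer
    perceptron, derives threshold rule sets from labeled training data,
    and summarises the laminar morphological composition of cortical
    regions (descriptive statistics, Kruskal-Wallis with Dunn post hoc,
    chi-square composition tests, factor analysis, t-SNE embeddings,
    ternary and radar summaries). Includes a synthetic-data generator
    that produces labeled soma contours per morphological class and
    assembles cortical columns with configurable layer compositions, so
    the full pipeline is testable without tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    grDevices,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
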