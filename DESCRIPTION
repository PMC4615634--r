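Package: odourspace
Title: Network Analysis of Odour Perceptual Spaces and Structure-Odour Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing collections of odour molecules annotated with
    free-text perceptual descriptors. Curates descriptions into dichotomous
    molecule-by-descriptor matrices, builds weighted descriptor co-occurrence
    networks with Erdos-Renyi null ensembles, discrete power-law degree fits
    (Kolmogorov-Smirnov x_min selection) and Louvain communities, compares
    odour networks against windowed bag-of-words semantic networks by graph
    Laplacian eigen-similarity, clusters molecules separately in perceptual
    and physico-chemical space (spectral embedding with X-means/BIC model
    selection) and quantifies their concordance with a pair-agreement Hubert
    index, and predicts perceptual classes from molecular descriptors with a
    random forest wrapped around correlation-based feature selection inside
    cross-validation. Includes generators for synthetic corpora, feature
    tables and token streams so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
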