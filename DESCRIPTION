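Package: patchentropy
Title: Patch-Based Spatio-Temporal Entropy Decomposition and Multiway
    Correspondence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatio-temporal structuring of categorical or
    compositional grid data through the landscape-ecology notion of patches.
    Builds spatial and temporal patches per category, classifies their sizes,
    shapes and ordinal (permutation) motifs, assembles multiway
    distribution-like tables from occurrences, k-co-occurrences or
    distance-ratio weights, and decomposes the information they carry with
    normalized Shannon entropy chains, mutual information, conditional-entropy
    ratio maps, and a weighted multiway correspondence analysis of the
    ratio-to-independence tensor with CTR tensors, CTR-entropy summaries and
    analytic positive rank-one splitting. Includes a seeded generator of
    compositional grid time series for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
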