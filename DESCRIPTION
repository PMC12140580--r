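Package: dynmod
Title: Dynamic Modularity of Windowed Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved modular analysis of multichannel
    physiological signal panels, built around resting-state functional MRI.
    Region-by-time panels are decomposed with the maximal-overlap discrete
    wavelet transform, turned into windowed wavelet-coherence networks with a
    shuffle-null coherence threshold, and partitioned into spatiotemporal
    modules by generalized Louvain maximization of the multilayer modularity
    quality function. Downstream metrics include cohesion strength and
    disjointedness of modular reconfiguration, module-allegiance matrices with
    recruitment and integration of labeled networks, symmetric nonnegative
    matrix factorization for summary-network derivation with rank-selection
    criteria, behavioral learning measures with validated k-means subgrouping
    and a PC1 learning score, and brain-behavior regression with leave-one-out
    cross-validation and permutation validation. A synthetic cohort generator
    with planted dynamic communities and linked learning curves makes every
    stage testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
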