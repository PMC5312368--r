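Package: stocsynet
Title: SRV Clustering, OPLS-DA and OR-STOCSY Network Reconstruction for 1D NMR Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference chain for staged-disease 1D 1H NMR metabolomics:
    high-resolution spectral bucketing, statistical recoupling of variables
    (SRV) into peak-coherent clusters, multivariate discrimination by PCA,
    PLS-DA and OPLS-DA with VIP and loading-correlation significance rules
    and response-permutation validation, recoupled and orthogonally filtered
    statistical total correlation spectroscopy (R-STOCSY/OR-STOCSY) for
    inter-metabolite correlation extraction, KGML-based bipartite
    metabolite-enzyme network reconstruction via shortest paths, and
    betweenness-centrality pathway-impact scoring with hypergeometric
    enrichment. A synthetic-data module generates group-structured spectra
    with known ground truth and toy pathway files so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
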