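Package: metacoupler
Title: Enzyme-Metabolite Coupling Analysis from Joint Transcriptomic and
    Metabolomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and exploits statistical coupling between metabolic
    enzyme expression and the levels of the metabolites their reactions
    consume or produce. Provides a genome-scale metabolic network container
    with reaction-gene-metabolite (RGM) triplet enumeration, per-condition
    Spearman association tables with FDR control and a permutation null for
    coupling enrichment, a balanced linear-kernel SVM classifier that scores
    every RGM triplet with a confidence level in [-1, 1], a generalized
    multiple linear regressor predicting per-sample metabolite levels from
    enzyme expression, bipartite gene-metabolite graph and pathway enrichment
    analyses, and Kaplan-Meier median-split survival screening of predicted
    metabolites. A synthetic cohort generator with planted couplings,
    hazard links and an ER-like label provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    survival,
    igraph,
    jsonlite,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
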