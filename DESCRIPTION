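Package: regulomeShift
Title: Regulome Shift Analysis via Bipartite Gene-Process Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterising the transcriptional
    regulome shift induced by knockdown of a transcription cofactor.
    Implements per-gene differential expression statistics on replicated
    expression matrices, construction of weighted bipartite gene to
    biological-process networks per condition, eigenvector-centrality
    rate-of-change screening for candidate functional complements,
    Louvain community detection, interacting-protein coverage set
    analysis of biological processes, histone peptide-array statistics,
    delta-delta-Ct fold changes, total-area-sums normalisation of
    SWATH proteomics tables, and single-site isothermal titration
    calorimetry simulation and nonlinear least-squares fitting. A
    seeded synthetic-data generator emulates the full study design so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
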