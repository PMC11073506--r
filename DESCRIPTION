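Package: sigrev
Title: Disease Gene Signatures and Transcriptomic Signature Reversion for
    Drug Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Constructs disease-associated gene signatures from RNA-seq
    counts by three routes (moderated linear models on log-TPM,
    negative-binomial generalized linear models, and latent-variable
    transfer learning), ranks drug perturbation profiles by the
    bi-directional weighted Kolmogorov-Smirnov connectivity score with
    normalized connectivity scores, Tau percentiles and permutation-based
    false discovery rates, filters repurposing candidates, and validates
    candidate sets by permutation enrichment against clinical-trial and
    viability-screen annotations, drug-drug similarity networks,
    protein-protein-interaction centrality, and ontology semantic
    similarity.  A synthetic-data generator with planted ground truth
    (differential genes, active latent variables, reverser drugs) makes
    every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    DESeq2,
    igraph,
    jsonlite,
    limma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
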