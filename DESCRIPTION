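Package: depnet
Title: Phenotype-Specific Gene Dependency Networks and Hub-Based
    Prognostic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed gene dependency networks underlying a binary
    phenotype from expression data: for each candidate gene pair the
    association between a target gene and the phenotype is contrasted between
    the low and high strata of a modulator gene via a conditional
    mutual-information score, with permutation-based significance. Downstream
    tools characterise network topology (power-law degree fits, hub selection
    by out-degree cutoff), select prognostic signature genes by resampled
    univariate Cox regression, compute GGI-style risk scores, evaluate risk
    stratification by log-rank tests, and summarise cross-dataset
    discrimination with the Dscore statistic and random-signature
    significance tests. Includes a seed-reproducible synthetic data generator
    with planted modulator-gated pairs and hazard genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
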