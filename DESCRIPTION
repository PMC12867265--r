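Package: rna5hmc
Title: Dual-Branch Deep Learning for RNA 5-Hydroxymethylcytosine Site
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts RNA 5-hydroxymethylcytosine (5hmC) modification sites
    in fixed-length 41-nt RNA sequences centred on a candidate cytosine.
    Implements a dual-branch neural classifier that combines an inception
    branch over learned per-nucleotide word embeddings with a transformer
    encoder branch over per-nucleotide language-model embeddings, together
    with fourteen classical nucleotide composition descriptors (NAC, DNC,
    TNC, Kmer, RCKmer, binary, ANF, EIIP, PseEIIP, ENAC, NCP, DAC, PseDNC,
    PCPseDNC), a nine-metric evaluation protocol, model-selection and
    ablation experiments with paired nonparametric tests, positional
    neighbourhood/enrichment analysis with Shapley-value attribution, and a
    seeded synthetic-data generator that plants a tunable A-rich/G-poor
    motif so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
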