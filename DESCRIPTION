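Package: protgeneval
Title: Evaluation of Conditional Protein Sequence Generators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metrics and baseline models for evaluating conditional generative
    models of protein sequences annotated with hierarchical functional labels.
    Implements the normalized spectrum (k-mer) kernel feature map, maximum mean
    discrepancy (MMD) two-sample statistics under linear and Gaussian kernels
    with permutation p-values, mean-reciprocal-rank (MRR) conditional
    consistency over a label DAG including a hierarchy-tolerant variant,
    diversity and novelty statistics (feature entropy, mean pairwise RKHS
    distance, nearest-neighbour distances, maximum percent identity, random
    mutagenesis ladders), and out-of-distribution Top-X accuracy for held-out
    label combinations. Ships desk-scale baseline generators (per-label and
    per-combination n-gram models, a miniature conditional Wasserstein GAN with
    gradient penalty, projection conditioning and an auxiliary classifier) and
    a simulator of hierarchically labelled protein-like corpora for testing the
    whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
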