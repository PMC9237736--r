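# Shared fixture builders; everything is generated in code at test time.

# tiny hand-specified dataset
toy_dataset <- function() {
  labeled_dataset(c("s1", "s2", "s3", "s4"),
                  c("ACDEFGHIKL", "MNPQRSTVWY", "ACACACACAC", "DEDEDEDEDE"),
                  list(c("T1"), c("T2"), c("T1", "T2"), c("T2")))
}

# chain DAG T3 -> T2 -> T1
chain_dag <- function() {
  ontology_dag(data.frame(child = c("T3", "T2"), parent = c("T2", "T1")))
}

# flat (edgeless) d-label corpus with strong per-label motif signal and short
# sequences; the training substrate for the conditional GAN tests
flat_corpus <- function(n, d = 3, seed = 1, signal = 0.8,
                        length_mean = 24, length_sd = 4,
                        length_min = 16, length_max = 32) {
  terms <- sprintf("T%02d", seq_len(d))
  cfg <- synthetic_config(dag = ontology_dag(terms = terms), signal = signal,
                          length_mean = length_mean, length_sd = length_sd,
                          length_min = length_min, length_max = length_max,
                          multilabel_rate = 0)
  generate_dataset(cfg, n, seed = seed)$data
}

# random normalized nonnegative embedding matrix (rows unit norm)
random_embedding <- function(n, p) {
  M <- matrix(runif(n * p), n, p)
  M / sqrt(rowSums(M^2))
}

# independent transitive-closure oracle: iterate direct-parent expansion on the
# raw edge list until a fixed point (no igraph)
closure_oracle <- function(labels, edges) {
  repeat {
    added <- FALSE
    for (t in labels) {
      ps <- edges$parent[edges$child == t]
      new <- setdiff(ps, labels)
      if (length(new)) { labels <- c(labels, new); added <- TRUE }
    }
    if (!added) break
  }
  sort(labels)
}
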