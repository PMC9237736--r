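test_that("generated corpora are ancestor-closed with every label represented", {
  cfg <- synthetic_config(d = 7)
  sim <- generate_dataset(cfg, 280, seed = 3)
  # true-path closure holds by construction: imputation is a no-op
  imp <- impute_true_path(sim$data, sim$dag)
  expect_identical(imp$labels, sim$data$labels)
  counts <- lengths(label_index(sim$data))
  expect_true(all(counts >= floor(280 / (2 * 7))))
  # determinism
  sim2 <- generate_dataset(cfg, 280, seed = 3)
  expect_identical(sim2$data$residues, sim$data$residues)
  expect_error(generate_dataset(cfg, 3), "n >= ")
})

test_that("signal = 1 plants every label's motif; signal = 0 plants none", {
  cfg1 <- synthetic_config(d = 3, branching = 2, signal = 1,
                           multilabel_rate = 0)
  sim1 <- generate_dataset(cfg1, 60, seed = 4)
  leaves <- setdiff(sim1$dag$terms, unique(sim1$dag$edges$parent))
  for (i in seq_along(sim1$data$ids)) {
    leaf <- intersect(sim1$data$labels[[i]], leaves)
    motif <- cfg1$motifs[[leaf]]
    expect_true(grepl(motif, sim1$data$residues[i], fixed = TRUE))
  }
  # signal = 0: background only; motif hits occur at chance level
  cfg0 <- synthetic_config(d = 3, signal = 0, multilabel_rate = 0)
  sim0 <- generate_dataset(cfg0, 60, seed = 5)
  hit_rate <- mean(vapply(seq_along(sim0$data$ids), function(i) {
    leaf <- intersect(sim0$data$labels[[i]],
                      setdiff(cfg0$dag$terms, unique(cfg0$dag$edges$parent)))
    grepl(cfg0$motifs[[leaf[1]]], sim0$data$residues[i], fixed = TRUE)
  }, logical(1)))
  expect_lt(hit_rate, 0.15)  # P(specific 3-mer in ~120 positions) ~ 0.015
})

test_that("per-label spectra separate strongly under high signal", {
  cfg <- synthetic_config(dag = ontology_dag(terms = sprintf("T%02d", 1:3)),
                          signal = 0.5, multilabel_rate = 0, length_mean = 80,
                          length_sd = 10, length_min = 50, length_max = 120)
  sim <- generate_dataset(cfg, 600, seed = 6)
  leaves <- setdiff(sim$dag$terms, unique(sim$dag$edges$parent))
  idx <- label_index(sim$data)
  e <- spectrum_embedder(3)
  embs <- lapply(leaves, function(t) {
    X <- embed_sequences(ds_subset(sim$data, idx[[t]]), e)
    list(a = X[seq_len(nrow(X) %/% 2), ], b = X[-seq_len(nrow(X) %/% 2), ])
  })
  within <- vapply(embs, function(p) mmd(p$a, p$b)$mmd, numeric(1))
  between <- c()
  for (i in 1:2) for (j in (i + 1):3)
    between <- c(between, mmd(embs[[i]]$a, embs[[j]]$a)$mmd)
  expect_gt(min(between), 5 * max(within))
})

test_that("OOD splits divert the combination and size distractors correctly", {
  cfg <- synthetic_config(d = 7, signal = 1, multilabel_rate = 0.1)
  leaves <- setdiff(cfg$dag$terms, unique(cfg$dag$edges$parent))
  holdout <- leaves[1:2]
  sp <- generate_ood_split(cfg, 800, holdout, multiplier = 2, ood_rate = 0.05,
                           seed = 8)
  # no training sequence carries the full combination
  expect_false(any(vapply(sp$train$labels, function(l) all(holdout %in% l),
                          logical(1))))
  expect_true(all(vapply(sp$ood$labels, function(l) all(holdout %in% l),
                         logical(1))))
  expect_equal(length(sp$distractors$ids), 2 * length(sp$ood$ids))
  expect_true(all(sp$distractors$ids %in% sp$train$ids))
  # with signal = 1 the held-out sequences carry the motifs of BOTH labels
  for (i in seq_along(sp$ood$ids)) {
    for (t in holdout)
      expect_true(grepl(cfg$motifs[[t]], sp$ood$residues[i], fixed = TRUE))
  }
  expect_error(generate_ood_split(cfg, 100, c("TX")), "not in DAG")
})

test_that("synthetic FASTA/TSV output round-trips through the readers", {
  cfg <- synthetic_config(d = 7)
  sim <- generate_dataset(cfg, 60, seed = 9)
  dir <- withr::local_tempdir()
  write_fasta(sim$data, file.path(dir, "s.fasta"))
  write_labels(sim$data, file.path(dir, "l.tsv"))
  write_dag(sim$dag, file.path(dir, "d.tsv"))
  back <- read_labels(file.path(dir, "l.tsv"),
                      read_fasta(file.path(dir, "s.fasta")))
  expect_identical(back$residues, sim$data$residues)
  expect_identical(back$labels, sim$data$labels)
  dag <- read_dag(file.path(dir, "d.tsv"))
  expect_equal(dag$terms, sim$dag$terms)
})
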