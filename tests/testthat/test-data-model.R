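test_that("FASTA reading preserves order, uppercases and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "acde", ">s2", "MNPQ", "RSTV"), f)
  ds <- read_fasta(f)
  expect_equal(ds$ids, c("s1", "s2"))
  expect_equal(ds$residues, c("ACDE", "MNPQRSTV"))
  expect_equal(lengths(ds$labels), c(0L, 0L))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds, out)
  expect_equal(read_fasta(out)$residues, ds$residues)

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_length(read_fasta(empty)$ids, 0)
})

test_that("strict FASTA reading names offending non-standard characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACBDE"), f)
  expect_error(read_fasta(f, strict = TRUE), "B")
  expect_equal(read_fasta(f, strict = FALSE)$residues, "ACBDE")
})

test_that("label TSV attachment is set-valued and drops unlabelled sequences", {
  ds <- labeled_dataset(c("s1", "s2"), c("ACDE", "MNPQ"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tT1", "s1\tT2", "s1\tT1"), f)  # duplicate pair
  expect_message(out <- read_labels(f, ds), "excluded")
  expect_equal(out$ids, "s1")
  expect_equal(out$labels[[1]], c("T1", "T2"))
  expect_equal(out$vocabulary, c("T1", "T2"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sX\tT1", bad)
  expect_error(read_labels(bad, ds), "sX")
})

test_that("label round-trip through TSV preserves assignments", {
  ds <- toy_dataset()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels(ds, f)
  back <- read_labels(f, labeled_dataset(ds$ids, ds$residues))
  expect_equal(back$labels, ds$labels)
})

test_that("true-path imputation matches a brute-force closure and is idempotent", {
  dag <- chain_dag()
  ds <- labeled_dataset("s", "ACDEF", list("T3"))
  imp <- impute_true_path(ds, dag)
  expect_equal(imp$labels[[1]], c("T1", "T2", "T3"))
  # independent fixed-point oracle on the raw edge list
  expect_equal(imp$labels[[1]], closure_oracle("T3", dag$edges))
  expect_equal(impute_true_path(imp, dag)$labels, imp$labels)
  # root only: unchanged
  root <- labeled_dataset("r", "ACDEF", list("T1"))
  expect_equal(impute_true_path(root, dag)$labels[[1]], "T1")
  # label sets only ever grow
  expect_true(all(mapply(function(a, b) all(a %in% b),
                         ds$labels, imp$labels)))
  expect_error(impute_true_path(labeled_dataset("s", "ACDEF", list("TX")), dag),
               "TX")
})

test_that("filtering applies length, alphabet and per-label rules to a fixed point", {
  ds <- labeled_dataset(
    c("ok1", "ok2", "long", "bad", "rare"),
    c(strrep("A", 10), strrep("AC", 5), strrep("A", 2049), "ACXDE",
      strrep("C", 10)),
    list(c("T1"), c("T1"), c("T1"), c("T1"), c("T2")))
  out <- filter_dataset(ds, max_len = 2048, min_per_label = 2)
  expect_equal(out$ids, c("ok1", "ok2"))  # T2 below threshold -> rare unlabelled
  expect_equal(out$vocabulary, "T1")
  rem <- attr(out, "removed")
  expect_equal(unname(rem["too_long"]), 1L)
  expect_equal(unname(rem["nonstandard"]), 1L)
  # re-filtering is a no-op
  out2 <- filter_dataset(out, max_len = 2048, min_per_label = 2)
  expect_equal(out2$ids, out$ids)
  expect_equal(out2$vocabulary, out$vocabulary)
  # all-pass input unchanged
  clean <- toy_dataset()
  expect_equal(filter_dataset(clean, min_per_label = 1)$ids, clean$ids)
  expect_error(filter_dataset(ds, min_per_label = 10), "no sequences")
})

test_that("splitting is deterministic, partitions exactly, and routes OOD combos", {
  ds <- flat_corpus(300, d = 3, seed = 4)
  # add a multilabel combination to some sequences
  ds$labels[1:20] <- rep(list(c("T01", "T02")), 20)
  sp <- split_spec(ood_combinations = list(c("T01", "T02")), seed = 7)
  s1 <- split_dataset(ds, sp)
  s2 <- split_dataset(ds, sp)
  expect_identical(s1$train$ids, s2$train$ids)
  expect_identical(s1$val$ids, s2$val$ids)
  ood_ids <- s1$ood[["T01+T02"]]$ids
  expect_setequal(ood_ids, ds$ids[1:20])
  all_ids <- c(s1$train$ids, s1$val$ids, s1$test$ids, ood_ids)
  expect_setequal(all_ids, ds$ids)          # no loss
  expect_equal(anyDuplicated(all_ids), 0L)  # no overlap
  # exact-match mode keeps supersets in the splits
  ds$labels[[21]] <- c("T01", "T02", "T03")
  se <- split_dataset(ds, split_spec(ood_combinations = list(c("T01", "T02")),
                                     ood_match = "exact", seed = 7))
  expect_false(ds$ids[21] %in% se$ood[["T01+T02"]]$ids)
})

test_that("per-label minimum is enforced in val and test or reported infeasible", {
  ds <- flat_corpus(200, d = 4, seed = 9)
  sp <- split_spec(min_per_label = 5, seed = 3)
  s <- split_dataset(ds, sp)
  for (part in list(s$val, s$test)) {
    counts <- lengths(label_index(part))
    expect_true(all(counts >= 5))
  }
  expect_error(split_dataset(ds, split_spec(min_per_label = 1000, seed = 3)),
               "cannot place")
})

test_that("per-label subsetting is uniform without replacement and seeded", {
  ds <- flat_corpus(100, d = 2, seed = 5)
  sub <- subset_by_label(ds, "T01", 10, seed = 4)
  expect_length(sub$ids, 10)
  expect_true(all(vapply(sub$labels, function(l) "T01" %in% l, logical(1))))
  expect_equal(anyDuplicated(sub$ids), 0L)
  expect_identical(subset_by_label(ds, "T01", 10, seed = 4)$ids, sub$ids)
  n_t01 <- sum(vapply(ds$labels, function(l) "T01" %in% l, logical(1)))
  full <- subset_by_label(ds, "T01", n_t01, seed = 1)
  expect_identical(full$ids, ds$ids[vapply(ds$labels, function(l) "T01" %in% l,
                                           logical(1))])  # canonical order
  expect_error(subset_by_label(ds, "T01", n_t01 + 1), "only")
})

test_that("DAG construction validates acyclicity and answers hierarchy queries", {
  dag <- chain_dag()
  expect_equal(dag_parents(dag, "T3"), "T2")
  expect_equal(dag_children(dag, "T1"), "T2")
  expect_equal(dag_ancestors(dag, "T3"), c("T1", "T2"))
  expect_equal(dag_descendants(dag, "T1"), c("T2", "T3"))
  expect_error(ontology_dag(data.frame(child = c("A", "B"), parent = c("B", "A"))),
               "cycle")
})

test_that("edge TSV and OBO subset inputs normalize to the same DAG", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("T3\tT2", "T2\tT1"), tsv)
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T1", "", "[Term]", "id: T2", "is_a: T1 ! root",
               "", "[Term]", "id: T3", "is_a: T2"), obo)
  d1 <- read_dag(tsv); d2 <- read_dag(obo)
  expect_equal(d1$terms, d2$terms)
  expect_equal(d1$edges[order(d1$edges$child), ],
               d2$edges[order(d2$edges$child), ], ignore_attr = TRUE)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_dag(d1, out)
  expect_equal(read_dag(out)$edges, d1$edges)
})
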