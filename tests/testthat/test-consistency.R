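test_that("the MMD matrix equals element-wise recomputation by direct calls", {
  ds <- flat_corpus(90, d = 3, seed = 6)
  re <- per_label_embeddings(ds, size = 15, seed = 1)
  ge <- per_label_embeddings(ds, size = 15, seed = 2)
  M <- mmd_matrix(re, ge)
  for (i in seq_along(M$labels)) for (j in seq_along(M$labels)) {
    expect_equal(M$values[i, j],
                 mmd(re[[M$labels[j]]], ge[[M$labels[i]]])$mmd,
                 tolerance = 1e-9)
  }
  # gen = real -> zero diagonal
  M0 <- mmd_matrix(re, re)
  expect_equal(unname(diag(M0$values)), rep(0, 3), tolerance = 1e-12)
  expect_error(mmd_matrix(re, ge[c("T01", "T02")]), "label keys")
})

test_that("MRR matches hand-constructed rank patterns", {
  mk <- function(values, labels = sprintf("L%d", seq_len(nrow(values)))) {
    structure(list(labels = labels, values = values,
                   kernel = kernel_spec(), subset_size = NA, seed = NA),
              class = "mmd_matrix")
  }
  # zero diagonal, positive off-diagonal -> MRR 1
  V <- matrix(1, 3, 3); diag(V) <- 0
  expect_equal(mrr(mk(V)), 1)
  expect_equal(unname(per_label_ranks(mk(V))), c(1L, 1L, 1L))
  # d=2 with ranks (1, 2) -> (1 + 1/2)/2 = 0.75
  V2 <- matrix(c(0.1, 0.2, 0.2, 0.3), 2, 2, byrow = TRUE)
  expect_equal(mrr(mk(V2)), 0.75)
  # exact ties count against the model (pessimistic)
  V3 <- matrix(c(0.2, 0.2, 0.9, 0.1), 2, 2, byrow = TRUE)
  expect_equal(unname(per_label_ranks(mk(V3))), c(2L, 1L))
})

test_that("MRR is bounded in [1/d, 1] and invariant to monotone transforms", {
  set.seed(3)
  for (i in 1:20) {
    d <- sample(3:8, 1)
    V <- matrix(runif(d * d), d, d)
    M <- structure(list(labels = sprintf("L%d", 1:d), values = V,
                        kernel = kernel_spec(), subset_size = NA, seed = NA),
                   class = "mmd_matrix")
    v <- mrr(M)
    expect_gte(v, 1 / d)
    expect_lte(v, 1)
    M2 <- M; M2$values <- exp(3 * V) + 5  # strictly increasing transform
    expect_equal(mrr(M2), v)
  }
})

test_that("hierarchy-blind MRR excludes parent/child competitors", {
  # 3 labels: P parent of C, U unrelated. Generated-for-C is closer to P's
  # real set than to its own: rank 2 under MRR, rank 1 once P is excluded.
  dag <- ontology_dag(data.frame(child = "C", parent = "P"),
                      terms = c("C", "P", "U"))
  V <- matrix(c(
    0.10, 0.05, 0.90,   # target C: P (0.05) beats the diagonal (0.10)
    0.80, 0.10, 0.90,   # target P: diagonal best
    0.90, 0.80, 0.10),  # target U: diagonal best
    3, 3, byrow = TRUE,
    dimnames = list(c("C", "P", "U"), c("C", "P", "U")))
  M <- structure(list(labels = c("C", "P", "U"), values = V,
                      kernel = kernel_spec(), subset_size = NA, seed = NA),
                 class = "mmd_matrix")
  expect_equal(mrr(M), mean(c(1 / 2, 1, 1)))
  expect_equal(mrr_blind(M, dag), 1)
  # an unrelated competitor beating the diagonal still penalizes MRR_B
  V2 <- V; V2["C", c("P", "U")] <- c(0.90, 0.05)
  M2 <- M; M2$values <- V2
  expect_equal(mrr_blind(M2, dag), mrr(M2))
  expect_error(mrr_blind(M, chain_dag()), "missing from DAG")
})

test_that("MRR_B >= MRR on random matrices with a random hierarchy", {
  set.seed(11)
  dag <- synthetic_dag(7, branching = 2)
  for (i in 1:20) {
    V <- matrix(runif(49), 7, 7)
    M <- structure(list(labels = dag$terms, values = V,
                        kernel = kernel_spec(), subset_size = NA, seed = NA),
                   class = "mmd_matrix")
    expect_gte(mrr_blind(M, dag), mrr(M))
    expect_gte(mrr_blind(M, dag, transitive = TRUE), mrr_blind(M, dag))
  }
})

test_that("two-label DAG neighbours exclude each other entirely: MRR_B = 1", {
  dag <- ontology_dag(data.frame(child = "T2", parent = "T1"))
  V <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  M <- structure(list(labels = c("T1", "T2"), values = V,
                      kernel = kernel_spec(), subset_size = NA, seed = NA),
                 class = "mmd_matrix")
  expect_equal(mrr_blind(M, dag), 1)
})

test_that("randomized-label negative control approaches H_d/d", {
  ds <- flat_corpus(400, d = 5, seed = 13)
  X <- embed_sequences(ds)
  re <- per_label_embeddings(ds, size = 40, seed = 1)
  nc <- randomized_label_mrr(re, X, 40, repetitions = 200, seed = 2)
  expect_equal(nc$expectation, sum(1 / (1:5)) / 5)
  expect_lt(abs(nc$mean - nc$expectation), 3 * nc$se + 1e-12)
})

test_that("high-signal synthetic families give near-perfect MRR between draws", {
  # parameter recovery: independent draws from the same per-label distributions
  ds1 <- flat_corpus(300, d = 3, seed = 21)
  ds2 <- flat_corpus(300, d = 3, seed = 22)
  re <- per_label_embeddings(ds1, size = 80, seed = 1)
  ge <- per_label_embeddings(ds2, size = 80, seed = 2)
  expect_gte(mrr(mmd_matrix(re, ge)), 0.9)
})
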