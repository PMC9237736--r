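#' Top-X nearest-neighbour accuracy for out-of-distribution generation
#'
#' Scores generation conditioned on a label combination held out of training.
#' The candidate pool is the union of the held-out real sequences and real
#' distractor sequences (which do not carry the combination). A generated
#' sequence counts as accurate if at least one held-out real sequence is among
#' its `X` nearest pool members by Euclidean distance in embedding space; the
#' generated set itself is not part of the pool. Ties at the X-th distance are
#' broken by ascending pool index (held-out rows come first).
#'
#' @param gen Embedding matrix of generated sequences.
#' @param ood_real Embedding matrix of held-out true sequences.
#' @param distractors Embedding matrix of real sequences without the
#'   combination; by construction disjoint from `ood_real` (checked by row
#'   name when both are named).
#' @param X Neighbourhood size (typically 1 or 10).
#' @return Accuracy in `[0, 1]`.
#' @export
topx_accuracy <- function(gen, ood_real, distractors, X = 10) {
  if (ncol(gen) != ncol(ood_real) || ncol(gen) != ncol(distractors))
    stop("feature dimension mismatch")
  if (!is.null(rownames(ood_real)) && !is.null(rownames(distractors))) {
    overlap <- intersect(rownames(ood_real), rownames(distractors))
    if (length(overlap))
      stop("distractors overlap the held-out set: ",
           paste(head(overlap, 5), collapse = ", "))
  }
  pool <- rbind(as_dense(ood_real), as_dense(distractors))
  if (X > nrow(pool)) stop("X exceeds the pool size")
  n_ood <- nrow(ood_real)
  D2 <- cross_sqdist(as_dense(gen), pool)
  hits <- vapply(seq_len(nrow(D2)), function(i) {
    nb <- order(D2[i, ], seq_len(ncol(D2)))[seq_len(X)]
    any(nb <= n_ood)
  }, logical(1))
  mean(hits)
}

#' Label-blind random generation baseline
#'
#' Samples rows uniformly without replacement from a training embedding: the
#' "generator" that merely replays random training sequences, used as the
#' reference point for Top-X accuracy comparisons.
#'
#' @param train Embedding matrix (or `labeled_dataset`) to sample from.
#' @param size Number of rows to draw.
#' @param seed Integer seed.
#' @return An object of the same kind as `train` with `size` rows/sequences.
#' @export
random_generation_baseline <- function(train, size, seed = 1) {
  n <- if (inherits(train, "labeled_dataset")) length(train$ids) else nrow(train)
  if (size > n) stop("size exceeds the number of available rows")
  with_seed(seed, {
    idx <- sample.int(n, size)
    if (inherits(train, "labeled_dataset")) ds_subset(train, idx)
    else train[idx, , drop = FALSE]
  })
}
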