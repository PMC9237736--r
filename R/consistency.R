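#' Label-by-label MMD matrix between real and generated subsets
#'
#' Entry `(i, j)` is `MMD(real[[j]], gen[[i]])`: the distance of the set
#' generated for target label `i` to the real subset of label `j`. Row `i`
#' therefore ranks all real subsets by distance from generated set `i`; the
#' diagonal holds the on-target distances entering the MRR.
#'
#' @param real,gen Named lists of embedding matrices with identical label keys;
#'   subsets are expected to have been equalized to a common size upstream
#'   (see [subset_by_label()]).
#' @param kernel A [kernel_spec()].
#' @param subset_size,seed Optional provenance, recorded in the result.
#' @return An object of class `mmd_matrix` with fields `labels`, `values`
#'   (d-by-d matrix), `kernel`, `subset_size`, `seed`.
#' @export
mmd_matrix <- function(real, gen, kernel = kernel_spec(),
                       subset_size = NA_integer_, seed = NA_integer_) {
  if (!setequal(names(real), names(gen)) || is.null(names(real)))
    stop("label keys differ between real and gen: ",
         paste(union(setdiff(names(real), names(gen)),
                     setdiff(names(gen), names(real))), collapse = ", "))
  labels <- sort(names(real))
  d <- length(labels)
  if (d < 2) stop("need at least 2 labels")
  vals <- matrix(0, d, d, dimnames = list(gen = labels, real = labels))
  if (kernel$kind == "linear") {
    # mean-embedding shortcut: pairwise distances between per-label means,
    # computed per pair so that identical subsets give an exact zero
    mr <- t(vapply(labels, function(l) Matrix::colMeans(real[[l]]),
                   numeric(ncol(real[[labels[1]]]))))
    mg <- t(vapply(labels, function(l) Matrix::colMeans(gen[[l]]),
                   numeric(ncol(gen[[labels[1]]]))))
    for (i in seq_len(d)) for (j in seq_len(d))
      vals[i, j] <- sqrt(sum((mg[i, ] - mr[j, ])^2))
  } else {
    for (i in seq_len(d)) for (j in seq_len(d))
      vals[i, j] <- mmd(real[[labels[j]]], gen[[labels[i]]], kernel)$mmd
  }
  structure(list(labels = labels, values = vals, kernel = kernel,
                 subset_size = subset_size, seed = seed),
            class = "mmd_matrix")
}

#' @export
#' @method print mmd_matrix
print.mmd_matrix <- function(x, ...) {
  cat(sprintf("mmd_matrix: %d labels (%s kernel); mean diagonal %.4f, mean off-diagonal %.4f\n",
              length(x$labels), x$kernel$kind,
              mean(diag(x$values)), mean(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

# rank of the diagonal entry in each row, with pessimistic tie handling:
# competitors tied with the diagonal count against the model
row_ranks <- function(values, competitors = NULL) {
  d <- nrow(values)
  vapply(seq_len(d), function(i) {
    comp <- if (is.null(competitors)) setdiff(seq_len(d), i) else competitors[[i]]
    1L + sum(values[i, comp] <= values[i, i])
  }, integer(1))
}

#' Mean reciprocal rank of on-target MMD distances
#'
#' For each target label `i`, the rank of the on-target distance
#' `values[i, i]` among the distances of generated set `i` to all real
#' subsets; MRR is the mean of the reciprocal ranks. Maximal at 1 when every
#' generated set is closest in distribution to its own label's real subset;
#' a label-uninformed generator scores around `H_d / d` (the mean reciprocal
#' of a uniform rank). Exact ties are resolved pessimistically (a competitor
#' equal to the diagonal counts against the model), so degenerate inputs are
#' deterministic.
#'
#' @param M An [mmd_matrix()].
#' @return MRR in `(0, 1]`.
#' @export
mrr <- function(M) {
  mean(1 / row_ranks(M$values))
}

#' Hierarchy-tolerant mean reciprocal rank
#'
#' As [mrr()], but ranking errors arising from hierarchically adjacent labels
#' are not penalized: for target `i` the competitor set excludes labels that
#' are parents or children of `i` in the DAG (direct neighbours by default,
#' full ancestors/descendants with `transitive = TRUE`). Always >= [mrr()] on
#' the same matrix.
#'
#' @param M An [mmd_matrix()].
#' @param dag An [ontology_dag()] containing all matrix labels.
#' @param transitive Exclude all ancestors/descendants rather than only direct
#'   parents/children.
#' @return MRR_B in `(0, 1]`.
#' @export
mrr_blind <- function(M, dag, transitive = FALSE) {
  missing <- setdiff(M$labels, dag$terms)
  if (length(missing))
    stop("matrix label(s) missing from DAG: ", paste(missing, collapse = ", "))
  d <- length(M$labels)
  competitors <- lapply(seq_len(d), function(i) {
    t <- M$labels[i]
    excl <- if (transitive) c(dag_ancestors(dag, t), dag_descendants(dag, t))
            else c(dag_parents(dag, t), dag_children(dag, t))
    setdiff(seq_len(d), c(i, match(excl, M$labels)))
  })
  mean(1 / row_ranks(M$values, competitors))
}

#' Per-label diagonal ranks
#'
#' The rank of each label's on-target distance among all real subsets, as used
#' inside [mrr()]; the per-label breakdown of conditional performance.
#'
#' @param M An [mmd_matrix()].
#' @return Named integer vector of ranks (1 = best).
#' @export
per_label_ranks <- function(M) {
  setNames(row_ranks(M$values), M$labels)
}

#' Build per-label embedded subsets of a common size
#'
#' Convenience wrapper: for each vocabulary term, draw a fixed-size subset
#' ([subset_by_label()]) and embed it. Used to assemble the inputs of
#' [mmd_matrix()].
#'
#' @param dataset A `labeled_dataset`.
#' @param size Subset size per label; defaults to the largest feasible common
#'   size (the smallest per-label count).
#' @param embedder A [spectrum_embedder()].
#' @param normalize Passed to [embed_sequences()].
#' @param seed Integer seed (a distinct stream per label is derived from it).
#' @return Named list of embedding matrices, one per vocabulary term.
#' @export
per_label_embeddings <- function(dataset, size = NULL,
                                 embedder = spectrum_embedder(),
                                 normalize = TRUE, seed = 1) {
  idx <- label_index(dataset)
  counts <- lengths(idx)
  if (any(counts == 0))
    stop("vocabulary term(s) without sequences: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  if (is.null(size)) size <- min(counts)
  out <- vector("list", length(dataset$vocabulary))
  names(out) <- dataset$vocabulary
  for (i in seq_along(dataset$vocabulary)) {
    t <- dataset$vocabulary[i]
    sub <- subset_by_label(dataset, t, size, seed = seed + i)
    out[[t]] <- embed_sequences(sub, embedder, normalize = normalize)
  }
  out
}
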