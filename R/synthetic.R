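#' Build a small balanced term DAG
#'
#' Terms `T01..Td` arranged as a breadth-first tree of `child -> parent`
#' edges with a fixed branching factor: term 1 is the root, terms 2..b+1 its
#' children, and so on. Used as the default ontology of the simulator.
#'
#' @param d Number of terms.
#' @param branching Children per internal node (default 2).
#' @return An [ontology_dag()].
#' @export
synthetic_dag <- function(d, branching = 2) {
  stopifnot(d >= 1, branching >= 1)
  ids <- sprintf("T%02d", seq_len(d))
  if (d == 1) return(ontology_dag(terms = ids))
  parent <- ((seq_len(d) - 2L) %/% branching) + 1L  # BFS numbering
  ontology_dag(data.frame(child = ids[2:d], parent = ids[parent[2:d]]))
}

# default motif assignment: compositionally distinct 3-mers, homopolymers
# first (AAA, CCC, ...), then ABA patterns; deterministic in the term order
default_motifs <- function(terms, motif_len = 3) {
  n <- length(terms)
  pats <- character(0)
  for (a in AA_ALPHABET) pats <- c(pats, strrep(a, motif_len))
  if (n > length(pats)) {
    for (a in AA_ALPHABET) for (b in setdiff(AA_ALPHABET, a)) {
      half <- ceiling(motif_len / 2)
      pats <- c(pats, substr(paste0(strrep(paste0(a, b), half), a), 1, motif_len))
      if (length(pats) >= n) break
    }
  }
  if (n > length(pats)) stop("too many terms for the default motif catalogue")
  setNames(as.list(pats[seq_len(n)]), terms)
}

#' Configuration of the synthetic hierarchically labelled corpus
#'
#' The simulator emulates a labelled protein corpus at the level of label,
#' length and k-mer statistics: each sequence draws a leaf term of a small
#' ontology (labels closed under the ancestor relation by construction),
#' background residues from a fixed composition, and per-label k-mer motifs
#' overwritten into the sequence at a controllable rate. `signal = 0` yields
#' sequences statistically independent of their labels (a built-in negative
#' control); high signal yields strongly separated per-label k-mer spectra.
#'
#' @param d Number of ontology terms (vocabulary size).
#' @param branching DAG branching factor (see [synthetic_dag()]).
#' @param motifs Named list (term -> character vector of motifs over the
#'   standard alphabet, each at least 3 long); defaults to distinct
#'   compositionally separated 3-mers per term.
#' @param signal Motif insertion rate in `[0, 1]`: the number of motif copies
#'   is `Binomial(floor(L / motif_len), signal)` per sequence.
#' @param length_mean,length_sd,length_min,length_max Gaussian length model,
#'   truncated to `[length_min, length_max]`, `length_max <= 2048`.
#' @param background Residue frequency vector of length 20 (default uniform).
#' @param multilabel_rate Probability that a sequence carries one extra,
#'   non-ancestral leaf label (whose motifs are also inserted).
#' @param dag Optional [ontology_dag()] overriding the default balanced tree
#'   (e.g. an edgeless DAG for a flat label space); `d` is then taken from it.
#' @param seed Default seed used by [generate_dataset()] when none is given.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(d = 7, branching = 2, motifs = NULL, signal = 0.5,
                             length_mean = 120, length_sd = 30,
                             length_min = 30, length_max = 2048,
                             background = NULL, multilabel_rate = 0.1,
                             dag = NULL, seed = 1) {
  stopifnot(signal >= 0, signal <= 1, multilabel_rate >= 0, multilabel_rate <= 1,
            length_min >= 3, length_max <= 2048, length_min <= length_max)
  if (is.null(dag)) dag <- synthetic_dag(d, branching) else d <- length(dag$terms)
  if (is.null(motifs)) motifs <- default_motifs(dag$terms)
  motifs <- lapply(motifs, as.character)
  bad <- setdiff(unique(unlist(strsplit(unlist(motifs), ""))), AA_ALPHABET)
  if (length(bad)) stop("motif characters outside the alphabet: ",
                        paste(bad, collapse = ", "))
  mlens <- nchar(unlist(motifs))
  if (length(unique(mlens)) > 1)
    stop("all motifs must have the same length (slot-based insertion)")
  if (max(mlens) > length_min)
    stop("motif longer than the minimum sequence length")
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20, all(background >= 0))
  background <- background / sum(background)
  structure(list(d = d, branching = branching, dag = dag, motifs = motifs,
                 signal = signal, length_mean = length_mean,
                 length_sd = length_sd, length_min = length_min,
                 length_max = length_max, background = background,
                 multilabel_rate = multilabel_rate, seed = seed),
            class = "synthetic_config")
}

# leaves of the config DAG (terms without children)
config_leaves <- function(config) {
  setdiff(config$dag$terms, unique(config$dag$edges$parent))
}

# draw one sequence given its assigned leaf labels (character vector)
draw_sequence <- function(config, leaf_labels) {
  L <- round(rnorm(1, config$length_mean, config$length_sd))
  L <- min(max(L, config$length_min), config$length_max)
  ch <- sample(AA_ALPHABET, L, replace = TRUE, prob = config$background)
  motifs <- unlist(config$motifs[leaf_labels], use.names = FALSE)
  if (length(motifs) && config$signal > 0) {
    mlen <- nchar(motifs[1])
    slots <- L %/% mlen
    n_ins <- rbinom(1, slots, config$signal)
    if (n_ins > 0) {
      where <- sample.int(slots, n_ins)  # non-overlapping slot offsets
      which_m <- sample(motifs, n_ins, replace = TRUE)
      for (t in seq_len(n_ins)) {
        pos <- (where[t] - 1L) * mlen
        ch[pos + seq_len(mlen)] <- strsplit(which_m[t], "")[[1]]
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a hierarchically labelled protein-like corpus
#'
#' Each sequence draws a leaf label (stratified so every leaf, and hence every
#' term, is well represented), possibly an extra non-ancestral leaf label at
#' `multilabel_rate`, imputes all ancestors (true-path closure), draws a
#' length, fills positions from the background composition and overwrites
#' motif copies of its assigned leaf labels at rate `signal`. Deterministic
#' given the seed.
#'
#' @param config A [synthetic_config()].
#' @param n Number of sequences (`n >= d`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param force_combination Optional character vector of leaf terms: a
#'   fraction `force_rate` of sequences is assigned exactly this label
#'   combination (used to provision OOD holdout sets).
#' @param force_rate Fraction of sequences forced to the combination.
#' @return List with `data` (a `labeled_dataset` whose vocabulary is the full
#'   term set) and `dag` (the [ontology_dag()]).
#' @export
generate_dataset <- function(config, n, seed = config$seed,
                             force_combination = NULL, force_rate = 0) {
  stopifnot(n >= config$d)
  leaves <- config_leaves(config)
  anc <- dag_ancestor_table(config$dag)
  with_seed(seed, {
    leaf_assign <- sample(rep_len(leaves, n))
    forced <- logical(n)
    if (!is.null(force_combination) && force_rate > 0) {
      stopifnot(all(force_combination %in% config$dag$terms))
      forced[sample.int(n, max(1, round(force_rate * n)))] <- TRUE
    }
    ids <- sprintf("syn%05d", seq_len(n))
    residues <- character(n)
    labels <- vector("list", n)
    for (i in seq_len(n)) {
      if (forced[i]) {
        assigned <- force_combination
      } else {
        assigned <- leaf_assign[i]
        if (config$multilabel_rate > 0 && runif(1) < config$multilabel_rate) {
          others <- setdiff(leaves, c(assigned, anc[[assigned]]))
          if (length(others)) assigned <- c(assigned, sample(others, 1))
        }
      }
      labels[[i]] <- sort(unique(c(assigned,
                                   unlist(anc[assigned], use.names = FALSE))))
      residues[i] <- draw_sequence(config, assigned)
    }
    list(data = labeled_dataset(ids, residues, labels,
                                vocabulary = config$dag$terms),
         dag = config$dag)
  })
}

#' Simulate a corpus with a held-out label combination
#'
#' Generates a corpus in which a fraction of sequences carries exactly the
#' `holdout` label combination; those sequences are diverted to the `ood` set
#' (no training sequence carries the full combination), and distractors are
#' sampled from the remaining sequences at `multiplier` times the OOD size.
#'
#' @param config A [synthetic_config()].
#' @param n Total number of sequences.
#' @param holdout Character vector of leaf terms forming the held-out
#'   combination (must be DAG terms).
#' @param multiplier Distractor count as a multiple of the OOD count
#'   (typical range 2-30).
#' @param ood_rate Fraction of simulated sequences assigned the combination.
#' @param seed Integer seed.
#' @return List with `labeled_dataset` elements `train`, `ood`, `distractors`
#'   and the `dag`.
#' @export
generate_ood_split <- function(config, n, holdout, multiplier = 10,
                               ood_rate = 0.05, seed = config$seed) {
  missing <- setdiff(holdout, config$dag$terms)
  if (length(missing))
    stop("holdout label(s) not in DAG: ", paste(missing, collapse = ", "))
  sim <- generate_dataset(config, n, seed = seed,
                          force_combination = holdout, force_rate = ood_rate)
  ds <- sim$data
  carries <- vapply(ds$labels, function(l) all(holdout %in% l), logical(1))
  ood <- ds_subset(ds, carries)
  rest <- ds_subset(ds, !carries)
  n_dis <- min(multiplier * length(ood$ids), length(rest$ids))
  dis <- with_seed(seed + 1, ds_subset(rest, sort(sample.int(length(rest$ids), n_dis))))
  list(train = rest, ood = ood, distractors = dis, dag = sim$dag)
}

#' Mean reciprocal rank of a label-randomized negative control
#'
#' The worst-case conditional generator: per-label "generated" sets are
#' assembled from the corpus with label assignments randomized (each set is a
#' uniform sample of sequences regardless of label), evaluated against the
#' real per-label subsets and averaged over repetitions. Its expectation is
#' the mean reciprocal of a uniform rank, `H_d / d`.
#'
#' @param real_embeddings Named list of real per-label embedding matrices
#'   (see [per_label_embeddings()]).
#' @param pool_embedding Embedding matrix of the whole corpus to sample
#'   randomized sets from.
#' @param size Sequences per randomized set.
#' @param repetitions Number of randomizations (>= 1).
#' @param seed Integer seed.
#' @return List with `mean`, `se` (standard error of the mean over
#'   repetitions), `per_rep` (the individual MRR values) and the analytic
#'   `expectation` `H_d / d`.
#' @export
randomized_label_mrr <- function(real_embeddings, pool_embedding, size,
                                 repetitions = 200, seed = 1) {
  d <- length(real_embeddings)
  labels <- names(real_embeddings)
  p <- ncol(pool_embedding)
  mr <- t(vapply(labels, function(l) Matrix::colMeans(real_embeddings[[l]]),
                 numeric(p)))
  n_pool <- nrow(pool_embedding)
  vals <- with_seed(seed, vapply(seq_len(repetitions), function(rep) {
    pick <- matrix(sample.int(n_pool, d * size, replace = n_pool < d * size),
                   nrow = size)
    mg <- t(vapply(seq_len(d), function(i)
      Matrix::colMeans(pool_embedding[pick[, i], , drop = FALSE]), numeric(p)))
    M <- structure(list(labels = labels,
                        values = sqrt(cross_sqdist(mg, mr)),
                        kernel = kernel_spec("linear"),
                        subset_size = size, seed = NA_integer_),
                   class = "mmd_matrix")
    mrr(M)
  }, numeric(1)))
  list(mean = mean(vals), se = sd(vals) / sqrt(repetitions), per_rep = vals,
       expectation = sum(1 / seq_len(d)) / d)
}
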