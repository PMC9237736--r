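#' Evaluate a generated corpus against a real reference
#'
#' Orchestrates the full metric pipeline: spectrum embedding, whole-set MMD
#' under the linear (normalized spectrum) and Gaussian kernels, the per-label
#' MMD matrix and its MRR / hierarchy-tolerant MRR_B / per-label ranks, and
#' diversity deltas (entropy and mean pairwise RKHS distance, generated minus
#' real). With `controls = TRUE` two reference rows are added: a positive
#' control (a disjoint half of the real set evaluated as if generated: MMD
#' near 0, MRR near 1) and a negative control simulating the worst model per
#' metric (randomized labels for MRR; a single constant sequence replicated
#' for MMD; a single repeated real sequence for the diversity deltas).
#'
#' @param real,gen `labeled_dataset`s over a common vocabulary (an error lists
#'   terms of `gen` missing from `real`).
#' @param dag Optional [ontology_dag()]; required for MRR_B.
#' @param k Spectrum order (default 3).
#' @param subset_size Per-label subset size for the MMD matrix; defaults to
#'   the largest size available in both corpora.
#' @param bins Histogram bins for the entropy estimate (default 1000).
#' @param controls Add positive/negative control rows.
#' @param mrr_b_transitive Passed to [mrr_blind()].
#' @param seed Integer seed governing subset draws and controls.
#' @return An object of class `evaluation_report`.
#' @export
evaluate <- function(real, gen, dag = NULL, k = 3, subset_size = NULL,
                     bins = 1000, controls = FALSE, mrr_b_transitive = FALSE,
                     seed = 1) {
  missing <- setdiff(gen$vocabulary, real$vocabulary)
  if (length(missing))
    stop("generated vocabulary term(s) missing from the real corpus: ",
         paste(missing, collapse = ", "))
  vocab <- intersect(real$vocabulary, gen$vocabulary)
  real <- labeled_dataset(real$ids, real$residues,
                          lapply(real$labels, intersect, y = vocab), vocab)
  gen <- labeled_dataset(gen$ids, gen$residues,
                         lapply(gen$labels, intersect, y = vocab), vocab)
  emb <- spectrum_embedder(k)
  Xr <- embed_sequences(real, emb)
  Xg <- embed_sequences(gen, emb)

  counts_r <- lengths(label_index(real))
  counts_g <- lengths(label_index(gen))
  if (is.null(subset_size)) subset_size <- min(c(counts_r, counts_g))

  lin <- kernel_spec("linear")
  gau <- kernel_spec("gaussian")

  model_row <- function(Xg_, gen_, tag) {
    re <- per_label_embeddings(real, subset_size, emb, seed = seed)
    ge <- per_label_embeddings(gen_, subset_size, emb, seed = seed + 1000L)
    M <- mmd_matrix(re, ge, lin, subset_size = subset_size, seed = seed)
    div_r <- diversity(Xr, bins = bins, seed = seed)
    div_g <- diversity(Xg_, bins = bins, seed = seed)
    deltas <- delta_stats(div_g, div_r)
    list(model = tag,
         mmd = mmd(Xr, Xg_, lin)$mmd,
         gaussian_mmd = mmd(Xr, Xg_, gau)$mmd,
         mrr = mrr(M),
         mrr_b = if (!is.null(dag)) mrr_blind(M, dag, mrr_b_transitive) else NA_real_,
         delta_entropy = unname(deltas["delta_entropy"]),
         delta_distance = unname(deltas["delta_distance"]),
         per_label_ranks = as.list(per_label_ranks(M)))
  }

  rows <- list(model_row(Xg, gen, "model"))

  if (controls) {
    # positive control: a disjoint half of the real corpus as "generated"
    half <- with_seed(seed, sample.int(length(real$ids)))
    h1 <- ds_subset(real, sort(half[seq_len(length(half) %/% 2)]))
    h2 <- ds_subset(real, sort(half[(length(half) %/% 2 + 1):length(half)]))
    pos_size <- min(lengths(label_index(h1)), lengths(label_index(h2)),
                    subset_size)
    re1 <- per_label_embeddings(h1, pos_size, emb, seed = seed)
    re2 <- per_label_embeddings(h2, pos_size, emb, seed = seed + 2000L)
    Mpos <- mmd_matrix(re1, re2, lin, subset_size = pos_size, seed = seed)
    X1 <- embed_sequences(h1, emb); X2 <- embed_sequences(h2, emb)
    dpos <- delta_stats(diversity(X2, bins = bins, seed = seed),
                        diversity(X1, bins = bins, seed = seed))
    rows <- c(rows, list(list(
      model = "positive_control",
      mmd = mmd(X1, X2, lin)$mmd, gaussian_mmd = mmd(X1, X2, gau)$mmd,
      mrr = mrr(Mpos),
      mrr_b = if (!is.null(dag)) mrr_blind(Mpos, dag, mrr_b_transitive) else NA_real_,
      delta_entropy = unname(dpos["delta_entropy"]),
      delta_distance = unname(dpos["delta_distance"]),
      per_label_ranks = as.list(per_label_ranks(Mpos)))))

    # negative control: worst model per metric
    re <- per_label_embeddings(real, subset_size, emb, seed = seed)
    neg_mrr <- randomized_label_mrr(re, Xr, subset_size,
                                    repetitions = 50, seed = seed)
    const_seq <- strrep("A", max(30, k))
    Xconst <- embed_sequences(rep(const_seq, 50), emb)
    rep_idx <- with_seed(seed, sample.int(length(real$ids), 1))
    Xrep <- embed_sequences(rep(real$residues[rep_idx], 50), emb)
    dneg <- delta_stats(diversity(Xrep, bins = bins, seed = seed),
                        diversity(Xr, bins = bins, seed = seed))
    rows <- c(rows, list(list(
      model = "negative_control",
      mmd = mmd(Xr, Xconst, lin)$mmd, gaussian_mmd = mmd(Xr, Xconst, gau)$mmd,
      mrr = neg_mrr$mean, mrr_b = NA_real_,
      delta_entropy = unname(dneg["delta_entropy"]),
      delta_distance = unname(dneg["delta_distance"]),
      per_label_ranks = NULL)))
  }

  structure(list(rows = rows,
                 provenance = list(k = k, subset_size = subset_size,
                                   bins = bins, seed = seed,
                                   d = length(vocab),
                                   n_real = length(real$ids),
                                   n_gen = length(gen$ids))),
            class = "evaluation_report")
}

#' Top-X accuracies for a set of held-out label combinations
#'
#' @param gen Embedding matrix of sequences generated for the combination.
#' @param ood_real,distractors Embedding matrices (see [topx_accuracy()]).
#' @param X Integer vector of neighbourhood sizes (default `c(1, 10)`).
#' @return Named numeric vector `top1`, `top10`, ... of accuracies.
#' @export
ood_report_row <- function(gen, ood_real, distractors, X = c(1, 10)) {
  setNames(vapply(X, function(x) topx_accuracy(gen, ood_real, distractors, x),
                  numeric(1)),
           paste0("top", X))
}

#' @export
#' @method print evaluation_report
print.evaluation_report <- function(x, ...) {
  cols <- c("model", "mmd", "gaussian_mmd", "mrr", "mrr_b",
            "delta_entropy", "delta_distance")
  hdr <- c("Model", "MMD", "Gauss.MMD", "MRR", "MRR_B", "dEntropy", "dDistance")
  fmt <- function(v) if (is.character(v)) sprintf("%-18s", v)
                     else if (is.na(v)) sprintf("%9s", "-")
                     else sprintf("%9.3f", v)
  cat(paste(c(sprintf("%-18s", hdr[1]), sprintf("%9s", hdr[-1])),
            collapse = " "), "\n")
  for (r in x$rows)
    cat(paste(vapply(cols, function(cn) fmt(r[[cn]]), character(1)),
              collapse = " "), "\n")
  cat(sprintf("(k=%d, subset size %d, d=%d, %d real / %d generated, seed %d)\n",
              x$provenance$k, x$provenance$subset_size, x$provenance$d,
              x$provenance$n_real, x$provenance$n_gen, x$provenance$seed))
  invisible(x)
}

#' Write an evaluation report as JSON and aligned TSV
#'
#' @param report An `evaluation_report`.
#' @param path Output path; `.json` is written there, and a `.tsv` twin next
#'   to it (extension swapped) with the main metric columns.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(rows = report$rows, provenance = report$provenance),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  tsv <- sub("\\.json$", ".tsv", path)
  if (tsv == path) tsv <- paste0(path, ".tsv")
  cols <- c("model", "mmd", "gaussian_mmd", "mrr", "mrr_b",
            "delta_entropy", "delta_distance")
  tab <- do.call(rbind, lapply(report$rows, function(r)
    data.frame(lapply(setNames(cols, cols), function(cn) {
      v <- r[[cn]]; if (is.null(v)) NA else v
    }))))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path Path written by [write_report()].
#' @return An `evaluation_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(obj$rows, function(r) {
    for (nm in c("mmd", "gaussian_mmd", "mrr", "mrr_b",
                 "delta_entropy", "delta_distance"))
      r[[nm]] <- if (is.null(r[[nm]])) NA_real_ else as.numeric(r[[nm]])
    if (!is.null(r$per_label_ranks))
      r$per_label_ranks <- lapply(r$per_label_ranks, as.integer)
    r
  })
  structure(list(rows = rows, provenance = obj$provenance),
            class = "evaluation_report")
}

#' Evaluate from files on disk
#'
#' File-based wrapper around [evaluate()]: reads FASTA sequences, label TSVs
#' and (optionally) a DAG, imputes the true-path closure on both corpora when
#' a DAG is given, and runs the metric pipeline.
#'
#' @param real_fasta,real_labels,gen_fasta,gen_labels File paths.
#' @param dag_path Optional DAG file ([read_dag()] formats).
#' @param ... Passed to [evaluate()].
#' @return An `evaluation_report`.
#' @export
evaluate_files <- function(real_fasta, real_labels, gen_fasta, gen_labels,
                           dag_path = NULL, ...) {
  real <- read_labels(real_labels, read_fasta(real_fasta))
  gen <- read_labels(gen_labels, read_fasta(gen_fasta))
  dag <- NULL
  if (!is.null(dag_path)) {
    dag <- read_dag(dag_path)
    real <- impute_true_path(real, dag)
    gen <- impute_true_path(gen, dag)
  }
  evaluate(real, gen, dag = dag, ...)
}
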