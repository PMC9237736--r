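#' Construct a labelled protein sequence dataset
#'
#' The central container of the package: sequence ids, residue strings over the
#' 20-letter standard amino-acid alphabet, and per-sequence label sets over a
#' fixed, lexicographically ordered vocabulary of term ids.
#'
#' @param ids Character vector of unique, non-empty sequence ids.
#' @param residues Character vector of residue strings (same length as `ids`).
#' @param labels List of character vectors (one per sequence) of term ids, or
#'   `NULL` for an unlabelled dataset.
#' @param vocabulary Optional explicit label vocabulary. Defaults to the sorted
#'   distinct terms appearing in `labels`.
#' @return An object of class `labeled_dataset` with fields `ids`, `residues`,
#'   `labels` and `vocabulary`.
#' @export
labeled_dataset <- function(ids, residues, labels = NULL, vocabulary = NULL) {
  ids <- as.character(ids)
  residues <- toupper(as.character(residues))
  if (length(ids) != length(residues))
    stop("ids and residues must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (length(residues) && any(!nzchar(residues))) stop("residue strings must be non-empty")
  if (is.null(labels)) {
    labels <- rep(list(character(0)), length(ids))
  } else {
    if (length(labels) != length(ids)) stop("labels must have one entry per sequence")
    labels <- unname(lapply(labels, function(l) sort(unique(as.character(l)))))
  }
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(labels)))
  } else {
    vocabulary <- sort(unique(as.character(vocabulary)))
    extra <- setdiff(unlist(labels), vocabulary)
    if (length(extra))
      stop("labels outside the supplied vocabulary: ", paste(extra, collapse = ", "))
  }
  structure(list(ids = ids, residues = residues, labels = labels,
                 vocabulary = vocabulary),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$ids)

#' @export
#' @method print labeled_dataset
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d sequences, %d vocabulary terms\n",
              length(x$ids), length(x$vocabulary)))
  if (length(x$ids)) {
    lens <- nchar(x$residues)
    cat(sprintf("  lengths %d-%d (median %d); %d sequences labelled\n",
                min(lens), max(lens), as.integer(median(lens)),
                sum(lengths(x$labels) > 0)))
  }
  invisible(x)
}

#' Subset a dataset by sequence index
#'
#' Keeps the vocabulary unchanged (terms may end up with zero members).
#'
#' @param dataset A `labeled_dataset`.
#' @param idx Integer or logical index into the sequences.
#' @return A `labeled_dataset`.
#' @export
ds_subset <- function(dataset, idx) {
  structure(list(ids = dataset$ids[idx], residues = dataset$residues[idx],
                 labels = dataset$labels[idx], vocabulary = dataset$vocabulary),
            class = "labeled_dataset")
}

#' Map each vocabulary term to the indices of sequences carrying it
#'
#' @param dataset A `labeled_dataset`.
#' @return Named list, one integer vector per vocabulary term.
#' @export
label_index <- function(dataset) {
  idx <- setNames(vector("list", length(dataset$vocabulary)), dataset$vocabulary)
  for (t in dataset$vocabulary) idx[[t]] <- integer(0)
  for (i in seq_along(dataset$labels)) {
    for (t in dataset$labels[[i]]) idx[[t]] <- c(idx[[t]], i)
  }
  idx
}

#' Read protein sequences from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; residues are
#' uppercased; record order is preserved. Labels are left empty.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, error when any sequence contains a character outside
#'   the 20-letter standard alphabet (the offending characters are named);
#'   if `FALSE` (default) such sequences are kept and can be removed later with
#'   [filter_dataset()].
#' @return A `labeled_dataset` with empty label sets.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0)
    return(labeled_dataset(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  residues <- toupper(as.character(set))
  if (strict) {
    bad <- nonstandard_residues(residues)
    offending <- which(lengths(bad) > 0)
    if (length(offending))
      stop("non-standard residues in ", ids[offending[1]], ": ",
           paste(bad[[offending[1]]], collapse = ", "))
  }
  labeled_dataset(ids, residues)
}

#' Write a dataset to FASTA
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output file path.
#' @param labels_in_header If `TRUE`, append the label set to each header as
#'   `id label1;label2`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path, labels_in_header = FALSE) {
  set <- Biostrings::BStringSet(dataset$residues)
  names(set) <- if (labels_in_header)
    paste(dataset$ids, vapply(dataset$labels, paste, character(1), collapse = ";"))
  else dataset$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Attach functional labels from a two-column TSV
#'
#' The file holds one `(sequence id, term id)` pair per row, no header.
#' Duplicate pairs are ignored (label sets). Sequences left without any label
#' after the join are excluded, mirroring the usual "at least one annotation"
#' corpus filter; the number excluded is reported via a message.
#'
#' @param path Path to the TSV.
#' @param dataset A `labeled_dataset` to annotate.
#' @param vocabulary Optional explicit vocabulary; defaults to the sorted
#'   distinct terms in the file.
#' @return A `labeled_dataset` with labels attached.
#' @export
read_labels <- function(path, dataset, vocabulary = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, colClasses = "character",
               col.names = c("id", "term"), quote = "", comment.char = ""),
    error = function(e) {
      if (length(readLines(path, n = 1)) == 0)
        data.frame(id = character(0), term = character(0))
      else stop("malformed label TSV: ", conditionMessage(e), call. = FALSE)
    })
  unknown <- setdiff(tab$id, dataset$ids)
  if (length(unknown))
    stop("label file references unknown sequence id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  labs <- split(tab$term, factor(tab$id, levels = dataset$ids))
  labels <- lapply(labs, function(l) sort(unique(l)))
  out <- labeled_dataset(dataset$ids, dataset$residues, labels, vocabulary)
  unlabeled <- lengths(out$labels) == 0
  if (any(unlabeled)) {
    message(sum(unlabeled), " sequence(s) without labels excluded")
    out <- ds_subset(out, !unlabeled)
  }
  out
}

#' Write the label assignment of a dataset as a two-column TSV
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(dataset, path) {
  n <- lengths(dataset$labels)
  tab <- data.frame(id = rep(dataset$ids, n), term = unlist(dataset$labels))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Close label sets under the ancestor relation (true-path rule)
#'
#' A sequence annotated with a term implicitly carries all of that term's
#' ancestors in the ontology; this imputes those missing labels. The operation
#' is idempotent and only ever grows label sets.
#'
#' If the dataset was built with an explicitly fixed vocabulary, imputed
#' ancestors are restricted to it; otherwise the vocabulary is extended to
#' cover all imputed terms.
#'
#' @param dataset A `labeled_dataset` whose labels are all DAG terms.
#' @param dag An [ontology_dag()].
#' @param restrict_to_vocabulary If `TRUE`, keep only imputed ancestors already
#'   in `dataset$vocabulary`.
#' @return A `labeled_dataset` with ancestor-closed label sets.
#' @export
impute_true_path <- function(dataset, dag, restrict_to_vocabulary = FALSE) {
  missing <- setdiff(unique(unlist(dataset$labels)), dag$terms)
  if (length(missing))
    stop("label(s) not in the DAG: ", paste(missing, collapse = ", "))
  anc <- dag_ancestor_table(dag)
  labels <- lapply(dataset$labels, function(l) {
    if (!length(l)) return(l)
    sort(unique(c(l, unlist(anc[l], use.names = FALSE))))
  })
  if (restrict_to_vocabulary) {
    labels <- lapply(labels, intersect, y = dataset$vocabulary)
    vocab <- dataset$vocabulary
  } else {
    vocab <- sort(unique(c(dataset$vocabulary, unlist(labels))))
  }
  labeled_dataset(dataset$ids, dataset$residues, labels, vocab)
}

#' Apply the standard corpus filters
#'
#' Removes sequences that exceed `max_len` or contain residues outside the
#' 20-letter alphabet, then drops vocabulary terms with fewer than
#' `min_per_label` remaining sequences (removing them from label sets), then
#' drops sequences left without any label. The three rules are iterated to a
#' fixed point, so re-filtering a filtered dataset is a no-op.
#'
#' @param dataset A `labeled_dataset`.
#' @param max_len Maximum sequence length kept (default 2048).
#' @param min_per_label Minimum number of sequences a vocabulary term must
#'   retain (default 1).
#' @return A filtered `labeled_dataset`; attribute `"removed"` holds the counts
#'   removed per rule (`too_long`, `nonstandard`, `unlabeled` sequences and
#'   `rare_terms`).
#' @export
filter_dataset <- function(dataset, max_len = 2048, min_per_label = 1) {
  removed <- c(too_long = 0L, nonstandard = 0L, unlabeled = 0L, rare_terms = 0L)
  too_long <- nchar(dataset$residues) > max_len
  removed["too_long"] <- sum(too_long)
  bad <- lengths(nonstandard_residues(dataset$residues)) > 0
  removed["nonstandard"] <- sum(bad & !too_long)
  keep <- !(too_long | bad)
  ids <- dataset$ids[keep]; res <- dataset$residues[keep]
  labels <- dataset$labels[keep]
  vocab <- dataset$vocabulary
  repeat {
    counts <- table(factor(unlist(labels), levels = vocab))
    rare <- names(counts)[counts < min_per_label]
    if (length(rare)) {
      removed["rare_terms"] <- removed["rare_terms"] + length(rare)
      vocab <- setdiff(vocab, rare)
      labels <- lapply(labels, setdiff, y = rare)
    }
    unlabeled <- lengths(labels) == 0
    if (any(unlabeled)) {
      removed["unlabeled"] <- removed["unlabeled"] + sum(unlabeled)
      ids <- ids[!unlabeled]; res <- res[!unlabeled]; labels <- labels[!unlabeled]
    }
    if (!length(rare) && !any(unlabeled)) break
  }
  if (!length(ids)) stop("no sequences left after filtering")
  out <- labeled_dataset(ids, res, labels, vocab)
  attr(out, "removed") <- removed
  out
}

#' Specify a train/validation/test split
#'
#' @param fractions Named numeric vector over `train`, `val`, `test`, summing
#'   to 1 (default 80/10/10).
#' @param ood_combinations List of character vectors: label combinations held
#'   out of all three splits.
#' @param min_per_label Minimum number of sequences each vocabulary term must
#'   have in both validation and test.
#' @param ood_match `"subset"` (default) holds a sequence out whenever its label
#'   set contains a combination as a subset; `"exact"` only on exact equality
#'   of the label set with the combination.
#' @param seed Integer seed making the split deterministic.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.8, val = 0.1, test = 0.1),
                       ood_combinations = list(), min_per_label = 0,
                       ood_match = c("subset", "exact"), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "val", "test") %in% names(fractions)))
  structure(list(fractions = fractions,
                 ood_combinations = lapply(ood_combinations, function(x) sort(unique(x))),
                 min_per_label = as.integer(min_per_label),
                 ood_match = match.arg(ood_match),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a dataset into train/validation/test plus OOD holdouts
#'
#' Sequences matching a held-out label combination are routed to `ood` and
#' appear in none of the three splits; the remainder is partitioned at the
#' requested fractions. If `min_per_label > 0`, sequences are greedily moved
#' from the training split into validation/test until every vocabulary term
#' reaches the minimum there (an error names the worst term if infeasible).
#' Deterministic given the spec's seed.
#'
#' @param dataset A `labeled_dataset`.
#' @param spec A [split_spec()].
#' @return List with `labeled_dataset` elements `train`, `val`, `test` and
#'   `ood` (one dataset per held-out combination, named by the combination).
#' @export
split_dataset <- function(dataset, spec) {
  n <- length(dataset$ids)
  is_ood <- rep(FALSE, n)
  ood_of <- rep(NA_integer_, n)
  for (ci in seq_along(spec$ood_combinations)) {
    combo <- spec$ood_combinations[[ci]]
    hit <- vapply(dataset$labels, function(l) {
      if (spec$ood_match == "subset") all(combo %in% l) else setequal(combo, l)
    }, logical(1))
    ood_of[hit & !is_ood] <- ci
    is_ood <- is_ood | hit
  }
  pool <- which(!is_ood)
  with_seed(spec$seed, {
    pool <- sample(pool)
    n_val <- round(length(pool) * spec$fractions["val"])
    n_test <- round(length(pool) * spec$fractions["test"])
    assign <- rep("train", length(pool))
    assign[seq_len(n_val)] <- "val"
    assign[n_val + seq_len(n_test)] <- "test"
    if (spec$min_per_label > 0) {
      for (part in c("val", "test")) {
        for (t in dataset$vocabulary) {
          carriers <- vapply(dataset$labels[pool], function(l) t %in% l, logical(1))
          have <- sum(carriers & assign == part)
          need <- spec$min_per_label - have
          if (need > 0) {
            movable <- which(carriers & assign == "train")
            if (length(movable) < need)
              stop(sprintf("cannot place %d sequences of label %s in %s (only %d available)",
                           spec$min_per_label, t, part,
                           have + length(movable)))
            assign[movable[seq_len(need)]] <- part
          }
        }
      }
      # verify: moving for one label cannot undo another (labels only gain)
    }
    ood <- lapply(seq_along(spec$ood_combinations), function(ci)
      ds_subset(dataset, which(ood_of == ci)))
    names(ood) <- vapply(spec$ood_combinations, paste, character(1), collapse = "+")
    list(train = ds_subset(dataset, sort(pool[assign == "train"])),
         val = ds_subset(dataset, sort(pool[assign == "val"])),
         test = ds_subset(dataset, sort(pool[assign == "test"])),
         ood = ood)
  })
}

#' Sample a fixed-size per-label subset
#'
#' Uniform sample without replacement of `size` sequences annotated with
#' `term`; a multilabel sequence may appear in several labels' subsets. When
#' `size` equals the label's total count the full subset is returned in
#' canonical (dataset) order. Deterministic given `seed`.
#'
#' @param dataset A `labeled_dataset`.
#' @param term A vocabulary term id.
#' @param size Number of sequences to draw.
#' @param seed Integer seed.
#' @return A `labeled_dataset` of exactly `size` sequences.
#' @export
subset_by_label <- function(dataset, term, size, seed = 1) {
  if (!term %in% dataset$vocabulary) stop("term not in vocabulary: ", term)
  idx <- which(vapply(dataset$labels, function(l) term %in% l, logical(1)))
  if (length(idx) < size)
    stop(sprintf("label %s has only %d sequences, %d requested",
                 term, length(idx), size))
  if (length(idx) == size) return(ds_subset(dataset, idx))
  with_seed(seed, ds_subset(dataset, sort(sample(idx, size))))
}
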