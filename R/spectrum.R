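#' Define a spectrum (k-mer count) feature map
#'
#' The spectrum feature map of order `k` counts the occurrences of every
#' length-`k` substring over the 20-letter amino-acid alphabet, giving
#' `20^k` features (8000 for the default `k = 3`). Columns are ordered
#' lexicographically, so embedding matrices are bit-comparable across runs.
#'
#' @param k k-mer length (default 3).
#' @param alphabet Ordered alphabet (default the 20 standard amino acids).
#' @return An object of class `spectrum_embedder`.
#' @export
spectrum_embedder <- function(k = 3, alphabet = aa_alphabet()) {
  stopifnot(k >= 1, length(alphabet) >= 2, !anyDuplicated(alphabet))
  structure(list(k = as.integer(k), alphabet = alphabet,
                 n_features = length(alphabet)^k),
            class = "spectrum_embedder")
}

#' @export
#' @method print spectrum_embedder
print.spectrum_embedder <- function(x, ...) {
  cat(sprintf("spectrum_embedder: k=%d over %d letters -> %d features\n",
              x$k, length(x$alphabet), x$n_features))
  invisible(x)
}

#' Names of the feature columns of a spectrum embedder
#'
#' @param embedder A [spectrum_embedder()].
#' @return Character vector of all k-mers in lexicographic (column) order.
#' @export
spectrum_features <- function(embedder) {
  grids <- rep(list(embedder$alphabet), embedder$k)
  # first position varies slowest -> lexicographic order
  do.call(paste0, expand.grid(rev(grids), stringsAsFactors = FALSE)[embedder$k:1])
}

#' Embed sequences as (normalized) spectrum k-mer count vectors
#'
#' Row `s`, column `c` holds the number of occurrences of k-mer `c` in sequence
#' `s` (overlapping windows; a length-`L` sequence has `L - k + 1` of them).
#' With `normalize = TRUE` each row is divided by its Euclidean norm, giving
#' the feature map of the normalized spectrum kernel: row inner products are
#' then kernel values in `[0, 1]`.
#'
#' @param seqs A `labeled_dataset` or a (possibly named) character vector of
#'   residue strings.
#' @param embedder A [spectrum_embedder()].
#' @param normalize Divide each row by its Euclidean norm (default `TRUE`).
#' @param sparse Return a sparse `Matrix::dgCMatrix` (default) or a dense base
#'   matrix. Both carry sequence ids as row names and are accepted
#'   interchangeably by all metric functions.
#' @return An n-by-`20^k` matrix of nonnegative reals with ids as row names.
#' @export
embed_sequences <- function(seqs, embedder = spectrum_embedder(),
                            normalize = TRUE, sparse = TRUE) {
  if (inherits(seqs, "labeled_dataset")) {
    ids <- seqs$ids; residues <- seqs$residues
  } else {
    residues <- as.character(seqs)
    ids <- if (!is.null(names(residues))) names(residues)
           else paste0("seq", seq_along(residues))
  }
  k <- embedder$k
  nf <- embedder$n_features
  nb <- length(embedder$alphabet)
  code <- rep(NA_integer_, 127L)
  code[utf8ToInt(paste(embedder$alphabet, collapse = ""))] <- 0:(nb - 1L)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_along(residues)) {
    r <- residues[s]
    L <- nchar(r)
    if (L < k) stop("sequence shorter than k: ", ids[s])
    cs <- code[utf8ToInt(r)]
    if (anyNA(cs)) stop("sequence ", ids[s], " contains characters outside the alphabet")
    idx <- cs[seq_len(L - k + 1L)]
    if (k > 1) for (off in 1:(k - 1L))
      idx <- idx * nb + cs[(1L + off):(L - k + 1L + off)]
    tab <- tabulate(idx + 1L, nbins = nf)
    nz <- which(tab > 0L)
    ii <- c(ii, rep.int(s, length(nz))); jj <- c(jj, nz); xx <- c(xx, tab[nz])
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(xx),
                            dims = c(length(residues), nf),
                            dimnames = list(ids, NULL))
  if (normalize) {
    nrm <- sqrt(Matrix::rowSums(M^2))
    M <- Matrix::Diagonal(x = 1 / nrm) %*% M
    dimnames(M) <- list(ids, NULL)
  }
  if (!sparse) M <- as.matrix(M)
  M
}

#' Load a precomputed embedding matrix from TSV/CSV
#'
#' Generic entry point for external feature spaces (e.g. learned protein
#' embeddings computed elsewhere). First column must hold unique sequence ids;
#' remaining columns must be numeric. All metric functions accept the result
#' interchangeably with spectrum embeddings.
#'
#' @param path Path to a TSV (or CSV, by extension) with a header row.
#' @return A dense numeric matrix with ids as row names.
#' @export
load_external_embedding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected an id column plus at least one feature column")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]]))
      stop(sprintf("non-numeric cell in column '%s' (column %d)",
                   colnames(vals)[j], j + 1L))
  }
  M <- as.matrix(vals)
  rownames(M) <- ids
  M
}

#' Save an embedding matrix as TSV
#'
#' Written with a header row (feature names if present, else `f1..fp`) and the
#' id column first, so that [load_external_embedding()] round-trips it.
#'
#' @param M Embedding matrix with ids as row names.
#' @param path Output file path.
#' @param feature_names Optional column names (e.g. [spectrum_features()]).
#' @return `path`, invisibly.
#' @export
save_embedding <- function(M, path, feature_names = NULL) {
  M <- as.matrix(M)
  cn <- if (!is.null(feature_names)) feature_names
        else if (!is.null(colnames(M))) colnames(M)
        else paste0("f", seq_len(ncol(M)))
  tab <- data.frame(id = rownames(M), M, check.names = FALSE)
  colnames(tab) <- c("id", cn)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
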