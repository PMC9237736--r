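#' Diversity statistics of an embedded sample
#'
#' Two heuristic diversity estimates used to detect mode collapse:
#' the average Shannon entropy over feature dimensions (each column's values
#' histogrammed into `bins` equal-width bins over `[0, 1]`; entropy in nats of
#' the empirical bin distribution, averaged over columns) and the average
#' pairwise RKHS distance between samples,
#' `sqrt(k(x,x) + k(y,y) - 2 k(x,y))`, averaged over unordered pairs.
#' For normalized features under the linear kernel the entropy is at most
#' `log(bins)` and the distance at most `sqrt(2)`.
#'
#' @param X Embedding matrix (rows = sequences); expected normalized when
#'   `kernel` is linear, so that feature values lie in `[0, 1]`.
#' @param bins Number of histogram bins per feature dimension (default 1000).
#' @param kernel A [kernel_spec()].
#' @param max_pairs Upper bound on the number of pairs used for the distance
#'   average; larger sets are subsampled with `seed`.
#' @param seed Seed for pair subsampling.
#' @return An object of class `diversity_stats` with fields `entropy`,
#'   `mean_pairwise_distance`, `n`, `bins`.
#' @export
diversity <- function(X, bins = 1000, kernel = kernel_spec(),
                      max_pairs = 1e6, seed = 1) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows for the pairwise distance")
  A <- as_dense(X)
  # column-wise histogram entropy over [0, 1]
  idx <- pmin(pmax(floor(A * bins) + 1L, 1L), bins)
  ent <- vapply(seq_len(ncol(idx)), function(j) {
    p <- tabulate(idx[, j], nbins = bins) / n
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  # mean pairwise RKHS distance
  sigma <- resolve_sigma(kernel, X, X)
  npairs <- n * (n - 1) / 2
  if (npairs <= max_pairs) {
    D2 <- cross_sqdist(A, A)
    if (kernel$kind == "gaussian") D2 <- 2 - 2 * exp(-D2 / (2 * sigma^2))
    D2[D2 < 0] <- 0
    mpd <- mean(sqrt(D2[upper.tri(D2)]))
  } else {
    mpd <- with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n - 1, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      d2 <- rowSums((A[i, , drop = FALSE] - A[j, , drop = FALSE])^2)
      if (kernel$kind == "gaussian") d2 <- 2 - 2 * exp(-d2 / (2 * sigma^2))
      mean(sqrt(pmax(d2, 0)))
    })
  }
  structure(list(entropy = mean(ent), mean_pairwise_distance = mpd,
                 n = n, bins = bins),
            class = "diversity_stats")
}

#' @export
#' @method print diversity_stats
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity_stats: entropy %.4f nats (%d bins), mean pairwise distance %.4f (n=%d)\n",
              x$entropy, x$bins, x$mean_pairwise_distance, x$n))
  invisible(x)
}

#' Signed diversity differences, generated minus reference
#'
#' @param gen,ref [diversity()] results computed with the same bin count.
#' @return Named numeric vector `c(delta_entropy, delta_distance)`.
#' @export
delta_stats <- function(gen, ref) {
  if (gen$bins != ref$bins)
    stop("bin counts differ: ", gen$bins, " vs ", ref$bins)
  c(delta_entropy = gen$entropy - ref$entropy,
    delta_distance = gen$mean_pairwise_distance - ref$mean_pairwise_distance)
}

#' Nearest-neighbour squared Euclidean distances
#'
#' For each row of `A`, the squared Euclidean distance to its nearest row of
#' `B`. Used as an overfitting control: the distribution of generated-to-train
#' distances should not be closer than test-to-train distances. When `A` and
#' `B` are the same matrix set `exclude_self = TRUE` to exclude each row's own
#' index (only that index; duplicate rows elsewhere still count).
#'
#' @param A,B Embedding matrices of equal feature dimension.
#' @param exclude_self Exclude the identical index (requires `nrow(A) == nrow(B)`).
#' @return Numeric vector of length `nrow(A)`.
#' @export
nn_squared_distances <- function(A, B, exclude_self = FALSE) {
  if (nrow(B) < 1) stop("reference set B is empty")
  if (ncol(A) != ncol(B)) stop("feature dimension mismatch")
  D2 <- cross_sqdist(as_dense(A), as_dense(B))
  if (exclude_self) {
    if (nrow(A) != nrow(B)) stop("exclude_self requires equally sized sets")
    diag(D2) <- Inf
  }
  apply(D2, 1, min)
}

#' Maximum percent identity of generated sequences to a reference set
#'
#' For each generated sequence, the maximum percent identity over the
#' reference set. With `method = "alignment"` identity comes from a global
#' alignment with unit match score, zero mismatch score and linear gap penalty
#' -1, as matches / alignment length x 100. With `method = "edit"` it is
#' `100 (1 - dL / max(L1, L2))` with `dL` the Levenshtein distance.
#' Candidate references are prefiltered per query to the `prefilter_topk`
#' nearest by spectrum cosine similarity for tractability.
#'
#' @param gen,reference `labeled_dataset`s or character vectors of residues.
#' @param prefilter_topk Number of reference candidates aligned per query
#'   (default 20; capped at the reference size).
#' @param method `"alignment"` (default) or `"edit"`.
#' @param k Spectrum order used for prefiltering.
#' @return Numeric vector in `[0, 100]`, one value per generated sequence.
#' @export
max_percent_identity <- function(gen, reference, prefilter_topk = 20,
                                 method = c("alignment", "edit"), k = 3) {
  method <- match.arg(method)
  gseq <- if (inherits(gen, "labeled_dataset")) gen$residues else as.character(gen)
  rseq <- if (inherits(reference, "labeled_dataset")) reference$residues
          else as.character(reference)
  if (!length(rseq)) stop("reference set is empty")
  topk <- min(prefilter_topk, length(rseq))
  emb <- spectrum_embedder(k)
  Gm <- embed_sequences(gseq, emb, normalize = TRUE)
  Rm <- embed_sequences(rseq, emb, normalize = TRUE)
  cos <- as.matrix(Matrix::tcrossprod(Gm, Rm))
  sub <- diag(1, length(AA_ALPHABET))  # match 1, mismatch 0
  dimnames(sub) <- list(AA_ALPHABET, AA_ALPHABET)
  vapply(seq_along(gseq), function(i) {
    cand <- order(cos[i, ], decreasing = TRUE)[seq_len(topk)]
    best <- 0
    for (j in cand) {
      pid <- if (method == "alignment") {
        al <- Biostrings::pairwiseAlignment(gseq[i], rseq[j], type = "global",
                                            substitutionMatrix = sub,
                                            gapOpening = 0, gapExtension = 1)
        aln_len <- nchar(as.character(Biostrings::alignedPattern(al)))
        100 * Biostrings::nmatch(al) / aln_len
      } else {
        100 * (1 - adist(gseq[i], rseq[j])[1, 1] / max(nchar(gseq[i]), nchar(rseq[j])))
      }
      if (pid > best) best <- pid
      if (best >= 100) break
    }
    best
  }, numeric(1))
}

#' Random point substitutions at a fixed per-site rate
#'
#' Every residue is independently replaced, with probability `rate`, by a
#' uniform draw from the 19 other standard residues (substitution only, no
#' indels).
#'
#' @param residues Character vector of residue strings.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Character vector of mutated residue strings.
#' @export
mutate_sequences <- function(residues, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    vapply(residues, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      hit <- runif(length(ch)) < rate
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit], function(orig)
          sample(setdiff(AA_ALPHABET, orig), 1), character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Random-mutagenesis MMD ladder
#'
#' Simulates random mutagenesis at a series of per-site substitution rates:
#' for each rate, mutates the input set, embeds it, and measures its MMD to a
#' reference embedding. Provides a reference curve of distributional shift per
#' unit of sequence change against which generated sequences can be compared.
#'
#' @param seqs A `labeled_dataset` or character vector of residues to mutate.
#' @param rates Numeric vector of substitution rates in `[0, 1]`.
#' @param reference_embed Embedding matrix of the reference set.
#' @param kernel A [kernel_spec()].
#' @param embedder A [spectrum_embedder()].
#' @param normalize Passed to [embed_sequences()].
#' @param seed Integer seed (a distinct stream per rate is derived from it).
#' @return Named list, one `mmd_result` per rate.
#' @export
mutagenesis_ladder <- function(seqs, rates, reference_embed,
                               kernel = kernel_spec(),
                               embedder = spectrum_embedder(),
                               normalize = TRUE, seed = 1) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  residues <- if (inherits(seqs, "labeled_dataset")) seqs$residues
              else as.character(seqs)
  out <- vector("list", length(rates))
  names(out) <- as.character(rates)
  for (i in seq_along(rates)) {
    mut <- mutate_sequences(residues, rates[i], seed = seed + i)
    M <- embed_sequences(mut, embedder, normalize = normalize)
    out[[i]] <- mmd(M, reference_embed, kernel)
  }
  out
}
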