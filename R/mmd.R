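#' Specify the kernel for MMD computations
#'
#' @param kind `"linear"` (the normalized spectrum kernel when applied to
#'   normalized spectrum embeddings) or `"gaussian"`.
#' @param sigma Bandwidth for the Gaussian kernel: a positive number or
#'   `"median"` (default) for the median heuristic, i.e. the median pairwise
#'   Euclidean distance over the pooled sample, resolved once per comparison.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "gaussian"), sigma = "median") {
  kind <- match.arg(kind)
  if (kind == "gaussian" && !identical(sigma, "median")) {
    sigma <- as.numeric(sigma)
    stopifnot(is.finite(sigma), sigma > 0)
  }
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

as_dense <- function(X) {
  if (is.matrix(X)) X else as.matrix(X)
}

# squared Euclidean cross-distances between rows of A and rows of B
cross_sqdist <- function(A, B) {
  an <- Matrix::rowSums(A^2)
  bn <- Matrix::rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * as.matrix(Matrix::tcrossprod(A, B))
  D2[D2 < 0] <- 0
  D2
}

resolve_sigma <- function(kernel, X, Y) {
  if (kernel$kind != "gaussian") return(NULL)
  if (!identical(kernel$sigma, "median")) return(kernel$sigma)
  P <- rbind(as_dense(X), as_dense(Y))
  D2 <- cross_sqdist(P, P)
  d <- sqrt(D2[upper.tri(D2)])
  s <- median(d)
  if (!is.finite(s) || s <= 0) s <- 1  # degenerate pooled sample
  s
}

gauss_gram <- function(A, B, sigma) {
  exp(-cross_sqdist(A, B) / (2 * sigma^2))
}

check_mmd_inputs <- function(X, Y) {
  if (nrow(X) < 1 || nrow(Y) < 1) stop("both sample sets must be non-empty")
  if (ncol(X) != ncol(Y))
    stop(sprintf("feature dimension mismatch: %d vs %d", ncol(X), ncol(Y)))
}

#' Maximum mean discrepancy between two embedded samples
#'
#' Computes the biased (V-statistic) MMD between the rows of `X` and `Y`.
#' Under the linear kernel this is exactly the Euclidean distance between the
#' two mean embedding vectors, `MMD^2 = || mean(X) - mean(Y) ||^2`; under the
#' Gaussian kernel `MMD^2 = mean k(x,x') + mean k(y,y') - 2 mean k(x,y)` with
#' `k(u,v) = exp(-||u-v||^2 / (2 sigma^2))`, diagonals included. The reported
#' `mmd` is the square root (round-off negatives clamped to 0 first).
#'
#' @param X,Y Embedding matrices (rows = sequences) of equal feature dimension.
#' @param kernel A [kernel_spec()].
#' @return An object of class `mmd_result` with fields `mmd`, `mmd_squared`,
#'   `n`, `m`, `kernel` and the resolved `sigma` (Gaussian only).
#' @export
mmd <- function(X, Y, kernel = kernel_spec()) {
  check_mmd_inputs(X, Y)
  sigma <- resolve_sigma(kernel, X, Y)
  if (kernel$kind == "linear") {
    delta <- Matrix::colMeans(X) - Matrix::colMeans(Y)
    m2 <- sum(delta^2)
  } else {
    A <- as_dense(X); B <- as_dense(Y)
    m2 <- mean(gauss_gram(A, A, sigma)) + mean(gauss_gram(B, B, sigma)) -
      2 * mean(gauss_gram(A, B, sigma))
  }
  structure(list(mmd = sqrt(max(0, m2)), mmd_squared = m2,
                 n = nrow(X), m = nrow(Y), kernel = kernel$kind,
                 sigma = sigma, pvalue = NULL),
            class = "mmd_result")
}

#' @export
#' @method print mmd_result
print.mmd_result <- function(x, ...) {
  cat(sprintf("MMD = %.6f (%s kernel%s; n=%d, m=%d%s)\n", x$mmd, x$kernel,
              if (!is.null(x$sigma)) sprintf(", sigma=%.4g", x$sigma) else "",
              x$n, x$m,
              if (!is.null(x$pvalue)) sprintf("; p=%.4g", x$pvalue) else ""))
  invisible(x)
}

#' Independent kernel-expansion oracle for MMD
#'
#' Recomputes the V-statistic MMD from the full Gram blocks,
#' `mean(K_XX) + mean(K_YY) - 2 mean(K_XY)`, for cross-checking [mmd()]
#' (which uses the mean-embedding shortcut for the linear kernel). Quadratic
#' in sample size; intended for tests and small inputs.
#'
#' @inheritParams mmd
#' @return The MMD value (square-root scale) as a plain number.
#' @export
mmd_kernel_oracle <- function(X, Y, kernel = kernel_spec()) {
  check_mmd_inputs(X, Y)
  A <- as_dense(X); B <- as_dense(Y)
  if (kernel$kind == "linear") {
    Kxx <- Matrix::tcrossprod(A, A); Kyy <- Matrix::tcrossprod(B, B)
    Kxy <- Matrix::tcrossprod(A, B)
  } else {
    sigma <- resolve_sigma(kernel, X, Y)
    Kxx <- gauss_gram(A, A, sigma); Kyy <- gauss_gram(B, B, sigma)
    Kxy <- gauss_gram(A, B, sigma)
  }
  m2 <- mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
  sqrt(max(0, m2))
}

#' Permutation p-value for the MMD two-sample test
#'
#' Pools the rows of both samples, reshuffles them into sets of the original
#' sizes `n_perm` times, and reports
#' `p = (1 + #{permuted MMD >= observed}) / (1 + n_perm)`. For the Gaussian
#' kernel the median-heuristic bandwidth is resolved once on the pooled sample
#' and held fixed across permutations.
#'
#' @inheritParams mmd
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the same seed reproduces the same p-value.
#' @return An `mmd_result` whose `pvalue` field is filled in.
#' @export
permutation_pvalue <- function(X, Y, kernel = kernel_spec(), n_perm = 199,
                               seed = 1) {
  stopifnot(n_perm >= 1)
  check_mmd_inputs(X, Y)
  if (kernel$kind == "gaussian") {
    kernel <- kernel_spec("gaussian", resolve_sigma(kernel, X, Y))
  }
  obs <- mmd(X, Y, kernel)
  P <- rbind(as_dense(X), as_dense(Y))
  n <- nrow(X)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(nrow(P))
      m <- mmd(P[p[seq_len(n)], , drop = FALSE],
               P[p[(n + 1):nrow(P)], , drop = FALSE], kernel)
      if (m$mmd >= obs$mmd - 1e-12) exceed <- exceed + 1L
    }
    obs$pvalue <- (1 + exceed) / (1 + n_perm)
  })
  obs
}

# two-sample Kolmogorov-Smirnov statistic for one numeric column
ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

#' Feature-wise Kolmogorov-Smirnov corroboration statistic
#'
#' Computes the two-sample KS statistic independently for every feature column
#' and aggregates as the mean over columns; a slower, rank-based corroboration
#' of the MMD comparison. Value in `[0, 1]`: 0 when the empirical marginals
#' coincide in every dimension, 1 when every dimension has disjoint support.
#'
#' @inheritParams mmd
#' @return Mean per-column KS statistic.
#' @export
featurewise_ks <- function(X, Y) {
  check_mmd_inputs(X, Y)
  A <- as_dense(X); B <- as_dense(Y)
  mean(vapply(seq_len(ncol(A)), function(j) ks_stat(A[, j], B[, j]), numeric(1)))
}
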