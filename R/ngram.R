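NGRAM_START <- "^"
NGRAM_STOP <- "$"

#' Fit an n-gram sequence model
#'
#' Counts all length-`n` windows over START-padded, STOP-terminated sequences:
#' each sequence is prefixed with `n - 1` START pads and suffixed with one STOP
#' symbol, and every (context of length `n - 1`, next symbol) pair is tallied.
#' Additive smoothing `alpha` is applied at sampling time, so the stored counts
#' are raw.
#'
#' @param seqs A `labeled_dataset` or character vector of residue strings.
#' @param n Model order (window length, default 3; contexts have length n-1).
#' @param alpha Additive pseudocount used when sampling (default 0.1).
#' @return An object of class `ngram_model`.
#' @export
fit_ngram <- function(seqs, n = 3, alpha = 0.1) {
  residues <- if (inherits(seqs, "labeled_dataset")) seqs$residues
              else as.character(seqs)
  if (!length(residues)) stop("empty corpus")
  stopifnot(n >= 1, alpha >= 0)
  n <- as.integer(n)
  ctxs <- character(0); syms <- character(0)
  for (r in residues) {
    padded <- paste0(strrep(NGRAM_START, n - 1L), r, NGRAM_STOP)
    L <- nchar(r)
    pos <- seq_len(L + 1L)
    ctxs <- c(ctxs, substring(padded, pos, pos + n - 2L))
    syms <- c(syms, substring(padded, pos + n - 1L, pos + n - 1L))
  }
  tab <- table(context = ctxs, symbol = syms)
  counts <- lapply(rownames(tab), function(cx) {
    v <- tab[cx, ]
    v <- v[v > 0]
    setNames(as.numeric(v), names(v))
  })
  names(counts) <- rownames(tab)
  structure(list(n = n, alpha = alpha, alphabet = AA_ALPHABET, counts = counts,
                 n_sequences = length(residues)),
            class = "ngram_model")
}

#' @export
#' @method print ngram_model
print.ngram_model <- function(x, ...) {
  cat(sprintf("ngram_model: n=%d, alpha=%g, %d contexts (fit on %d sequences)\n",
              x$n, x$alpha, length(x$counts), x$n_sequences))
  invisible(x)
}

#' Smoothed conditional distribution of an n-gram model
#'
#' @param model An `ngram_model`.
#' @param context Context string of length `n - 1` (START pads written as `^`).
#' @return Named probability vector over the 20 residues plus the STOP symbol,
#'   summing to 1.
#' @export
ngram_conditional <- function(model, context) {
  symbols <- c(model$alphabet, NGRAM_STOP)
  v <- setNames(rep(model$alpha, length(symbols)), symbols)
  obs <- model$counts[[context]]
  if (!is.null(obs)) v[names(obs)] <- v[names(obs)] + obs
  if (sum(v) == 0) stop("unseen context with alpha = 0: ", context)
  v / sum(v)
}

#' Sample sequences from an n-gram model
#'
#' Autoregressive sampling from the smoothed conditionals until STOP or
#' `max_len` residues. Deterministic given `seed`.
#'
#' @param model An `ngram_model`.
#' @param count Number of sequences to draw.
#' @param max_len Maximum residues per sequence (default 2048).
#' @param seed Integer seed.
#' @param min_len Suppress STOP until at least this many residues have been
#'   emitted (default 3, one k-mer at the default spectrum order, so samples
#'   can always be embedded).
#' @return Character vector of `count` residue strings.
#' @export
sample_ngram <- function(model, count, max_len = 2048, seed = 1, min_len = 3) {
  symbols <- c(model$alphabet, NGRAM_STOP)
  with_seed(seed, {
    vapply(seq_len(count), function(i) {
      ctx <- strrep(NGRAM_START, model$n - 1L)
      out <- character(0)
      repeat {
        p <- ngram_conditional(model, ctx)
        if (length(out) < min_len) p[NGRAM_STOP] <- 0
        if (sum(p) == 0) break
        sym <- sample(symbols, 1, prob = p)
        if (sym == NGRAM_STOP || length(out) >= max_len) break
        out <- c(out, sym)
        if (model$n > 1L)
          ctx <- paste0(substr(ctx, 2L, model$n - 1L), sym)
        if (length(out) >= max_len) break
      }
      paste(out, collapse = "")
    }, character(1))
  })
}

#' @export
simulate.ngram_model <- function(object, nsim = 1, seed = 1, max_len = 2048, ...) {
  sample_ngram(object, nsim, max_len = max_len, seed = seed)
}

#' Fit one n-gram model per label or per label combination
#'
#' `mode = "per_label"` (OpL) fits one model per vocabulary term on the
#' sequences carrying it, discarding multilabel structure (a multilabel
#' sequence enters several corpora). `mode = "per_combination"` (OpC) fits one
#' model per distinct exact label set present in the dataset.
#'
#' @param dataset A `labeled_dataset`.
#' @param mode `"per_label"` or `"per_combination"`.
#' @param n,alpha Passed to [fit_ngram()].
#' @return An object of class `ngram_ensemble`: a named list of `ngram_model`s
#'   (names are term ids, or `+`-joined sorted label sets), with the mode as
#'   attribute.
#' @export
fit_opl <- function(dataset, mode = c("per_label", "per_combination"),
                    n = 3, alpha = 0.1) {
  mode <- match.arg(mode)
  if (mode == "per_label") {
    idx <- label_index(dataset)
    keys <- names(idx)
    groups <- idx
  } else {
    keys0 <- vapply(dataset$labels, paste, character(1), collapse = "+")
    groups <- split(seq_along(keys0), keys0)
    keys <- names(groups)
  }
  models <- list()
  for (kx in keys) {
    g <- groups[[kx]]
    if (!length(g)) {
      warning("no sequences for key ", kx, "; skipped")
      next
    }
    models[[kx]] <- fit_ngram(dataset$residues[g], n = n, alpha = alpha)
  }
  structure(models, class = "ngram_ensemble", mode = mode)
}

#' @export
#' @method print ngram_ensemble
print.ngram_ensemble <- function(x, ...) {
  cat(sprintf("ngram_ensemble: %d models (%s)\n", length(x), attr(x, "mode")))
  invisible(x)
}

#' Generate a labelled dataset from an n-gram ensemble
#'
#' Draws `count` sequences from each component model and labels them with the
#' model's key (split on `+` for per-combination ensembles).
#'
#' @param ensemble An [fit_opl()] result.
#' @param count Sequences per model.
#' @param max_len,seed Passed to [sample_ngram()] (per-model streams derived
#'   from `seed`).
#' @param vocabulary Optional vocabulary for the returned dataset.
#' @return A `labeled_dataset` of `count * length(ensemble)` sequences.
#' @export
sample_opl <- function(ensemble, count, max_len = 2048, seed = 1,
                       vocabulary = NULL) {
  ids <- character(0); res <- character(0); labels <- list()
  for (i in seq_along(ensemble)) {
    kx <- names(ensemble)[i]
    s <- sample_ngram(ensemble[[i]], count, max_len = max_len, seed = seed + i)
    ids <- c(ids, sprintf("%s_gen%04d", kx, seq_len(count)))
    res <- c(res, s)
    labels <- c(labels, rep(list(strsplit(kx, "+", fixed = TRUE)[[1]]), count))
  }
  labeled_dataset(ids, res, labels, vocabulary)
}
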