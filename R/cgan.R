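# Miniature conditional WGAN-GP for protein sequences.
#
# Networks are small dense nets written in plain matrix algebra with manual
# backpropagation. The critic is the projection form
#   D(x, y) = v(y)' phi(x) + psi(phi(x))
# with phi a leaky-ReLU hidden layer, psi a linear scalar head and v a linear
# label projection; an auxiliary classifier head C_D shares phi and predicts
# the multilabel encoding. Because the hidden activation is piecewise linear,
# the gradient of the gradient-penalty term with respect to the critic
# parameters has a closed form (the second derivative of leaky ReLU vanishes
# almost everywhere), which is what the update uses.

PAD_CHANNEL <- 21L  # 20 amino acids + 1 padding/stop channel

lrelu <- function(a, leak) pmax(a, 0) + leak * pmin(a, 0)
lrelu_grad <- function(a, leak) ifelse(a > 0, 1, leak)
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Configuration of the miniature conditional WGAN-GP
#'
#' Desk-scale defaults: short fixed-length sequences, one hidden layer per
#' network. Sequences are one-hot encoded over 20 amino acids plus a padding
#' channel to fixed length `seq_len`; labels are multi-hot sums of one-hot
#' term encodings; in the generator the label vector is concatenated to the
#' latent noise input.
#'
#' @param seq_len Modelled sequence length (positions; longer training
#'   sequences are truncated, shorter ones padded).
#' @param latent_dim Dimension of the latent noise vector.
#' @param hidden_gen,hidden_disc Hidden layer widths.
#' @param ac_weight Auxiliary-classifier loss weight (gamma; 0 disables).
#' @param gp_weight Gradient-penalty weight (lambda, default 10).
#' @param lr_gen,lr_disc Adam learning rates.
#' @param beta1,beta2 Adam moment decay rates.
#' @param batch_size Minibatch size.
#' @param steps Training steps (one critic + one generator update each;
#'   critic:generator update ratio fixed at 1).
#' @param leak Leaky-ReLU negative slope.
#' @param seed Integer seed for initialization and training randomness.
#' @return An object of class `cgan_config`.
#' @export
cgan_config <- function(seq_len = 32, latent_dim = 16, hidden_gen = 64,
                        hidden_disc = 64, ac_weight = 2, gp_weight = 10,
                        lr_gen = 1e-3, lr_disc = 1e-3, beta1 = 0.5,
                        beta2 = 0.9, batch_size = 64, steps = 2000,
                        leak = 0.2, seed = 1) {
  structure(as.list(environment()), class = "cgan_config")
}

# one-hot encode residue strings to a (21 * L) x N matrix, truncating/padding
encode_onehot <- function(residues, L) {
  N <- length(residues)
  X <- matrix(0, PAD_CHANNEL * L, N)
  code <- rep(NA_integer_, 127L)
  code[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_along(AA_ALPHABET)
  for (s in seq_len(N)) {
    cs <- code[utf8ToInt(residues[s])]
    if (anyNA(cs)) stop("non-standard residue in sequence ", s)
    cs <- cs[seq_len(min(length(cs), L))]
    ch <- c(cs, rep(PAD_CHANNEL, L - length(cs)))
    X[(seq_len(L) - 1L) * PAD_CHANNEL + ch, s] <- 1
  }
  X
}

encode_labels <- function(label_sets, vocabulary) {
  Y <- matrix(0, length(vocabulary), length(label_sets))
  for (s in seq_along(label_sets)) {
    Y[match(intersect(label_sets[[s]], vocabulary), vocabulary), s] <- 1
  }
  Y
}

init_cgan_params <- function(config, d) {
  he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  D <- PAD_CHANNEL * config$seq_len
  list(
    gen = list(W1 = he(config$hidden_gen, config$latent_dim + d),
               b1 = numeric(config$hidden_gen),
               W2 = he(D, config$hidden_gen),
               b2 = numeric(D)),
    disc = list(W1 = he(config$hidden_disc, D),
                b1 = numeric(config$hidden_disc),
                w2 = rnorm(config$hidden_disc, sd = sqrt(1 / config$hidden_disc)),
                b2 = 0,
                V = he(config$hidden_disc, d) * 0.1,
                Wc = he(d, config$hidden_disc),
                bc = numeric(d)))
}

softmax_blocks <- function(logits, L) {
  dm <- dim(logits)
  dim(logits) <- c(PAD_CHANNEL, L * dm[2])
  logits <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(logits)
  P <- sweep(e, 2, colSums(e), "/")
  dim(P) <- dm
  P
}

gen_forward <- function(par, Z, Y, config) {
  Tm <- rbind(Z, Y)
  A <- par$W1 %*% Tm + par$b1
  H <- lrelu(A, config$leak)
  logits <- par$W2 %*% H + par$b2
  X <- softmax_blocks(logits, config$seq_len)
  list(Tm = Tm, A = A, H = H, logits = logits, X = X)
}

disc_forward <- function(par, X, Y, leak) {
  A <- par$W1 %*% X + par$b1
  H <- lrelu(A, leak)
  U <- par$w2 + par$V %*% Y
  score <- colSums(H * U) + par$b2
  clogits <- par$Wc %*% H + par$bc
  list(A = A, H = H, U = U, score = score, clogits = clogits)
}

# backprop through the critic given upstream gradients on score (vector per
# sample) and on the AC logits (matrix, or NULL). Returns parameter gradients
# and the gradient with respect to the input X.
disc_backprop <- function(par, X, Y, fwd, dscore, dclogits = NULL, leak = 0.2) {
  dH <- sweep(fwd$U, 2, dscore, "*")
  g <- list(Wc = NULL, bc = NULL)
  if (!is.null(dclogits)) {
    dH <- dH + crossprod(par$Wc, dclogits)
    g$Wc <- tcrossprod(dclogits, fwd$H)
    g$bc <- rowSums(dclogits)
  } else {
    g$Wc <- 0 * par$Wc; g$bc <- 0 * par$bc
  }
  dU <- sweep(fwd$H, 2, dscore, "*")
  dA <- dH * lrelu_grad(fwd$A, leak)
  list(W1 = tcrossprod(dA, X), b1 = rowSums(dA),
       w2 = rowSums(dU), b2 = sum(dscore),
       V = tcrossprod(dU, Y), Wc = g$Wc, bc = g$bc,
       dX = crossprod(par$W1, dA))
}

# gradient penalty lambda * mean((||grad_x D(xhat, y)|| - 1)^2) on interpolates
# xhat = eps * xr + (1 - eps) * xf, together with its closed-form parameter
# gradients (leaky-ReLU second derivative is zero a.e., so the activation
# pattern is treated as locally constant, as reverse-mode autodiff would).
gp_and_grads <- function(par, Xr, Xf, Y, lambda, leak, eps) {
  B <- ncol(Xr)
  Xh <- sweep(Xr, 2, eps, "*") + sweep(Xf, 2, 1 - eps, "*")
  A <- par$W1 %*% Xh + par$b1
  s <- lrelu_grad(A, leak)
  U <- par$w2 + par$V %*% Y
  us <- U * s
  gx <- crossprod(par$W1, us)          # per-sample input gradients, D x B
  norms <- sqrt(colSums(gx^2) + 1e-12)
  value <- lambda * mean((norms - 1)^2)
  coef <- lambda * 2 * (norms - 1) / (B * norms)
  gW1 <- tcrossprod(sweep(us, 2, coef, "*"), gx)
  gu <- sweep(s * (par$W1 %*% gx), 2, coef, "*")
  list(value = value, norms = norms,
       grads = list(W1 = gW1, b1 = 0 * par$b1,
                    w2 = rowSums(gu), b2 = 0,
                    V = tcrossprod(gu, Y),
                    Wc = 0 * par$Wc, bc = 0 * par$bc))
}

# numerically stable per-label binary cross-entropy from logits
bce_from_logits <- function(clogits, Ytrue) {
  mean(colSums(pmax(clogits, 0) - clogits * Ytrue + log1p(exp(-abs(clogits)))))
}

adam_step <- function(par, grads, state, lr, beta1, beta2, t, eps = 1e-8) {
  for (nm in names(grads)) {
    if (is.null(par[[nm]])) next
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

adam_init <- function(par) {
  lapply(par, function(p) list(m = 0 * p, v = 0 * p))
}

add_grads <- function(a, b) {
  for (nm in names(b)) if (nm != "dX") a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

#' Train the miniature conditional WGAN-GP
#'
#' Wasserstein GAN with gradient penalty and two conditioning mechanisms:
#' a projection discriminator (inner product of a linear label projection with
#' the critic's hidden representation) and an auxiliary classifier whose
#' per-label binary cross-entropy, weighted by `ac_weight`, is added to both
#' players' losses (on real and generated samples for the critic, on generated
#' samples for the generator). The critic output activation is the identity
#' (Wasserstein convention). Training alternates one critic and one generator
#' Adam update per step.
#'
#' @param train A `labeled_dataset` (its vocabulary defines the label space).
#' @param config A [cgan_config()].
#' @return An object of class `cgan_model` holding the parameters, config,
#'   vocabulary and per-step loss traces. An error naming the step index is
#'   raised if a loss becomes non-finite.
#' @export
train_cgan <- function(train, config = cgan_config()) {
  stopifnot(inherits(train, "labeled_dataset"), length(train$ids) > 0,
            length(train$vocabulary) > 0)
  vocab <- train$vocabulary
  d <- length(vocab)
  with_seed(config$seed, {
    Xall <- encode_onehot(train$residues, config$seq_len)
    Yall <- encode_labels(train$labels, vocab)
    par <- init_cgan_params(config, d)
    st_d <- adam_init(par$disc)
    st_g <- adam_init(par$gen)
    B <- min(config$batch_size, ncol(Xall))
    loss_d <- loss_g <- numeric(config$steps)
    for (step in seq_len(config$steps)) {
      idx <- sample.int(ncol(Xall), B, replace = ncol(Xall) < B)
      Xr <- Xall[, idx, drop = FALSE]
      Yr <- Yall[, idx, drop = FALSE]
      Z <- matrix(rnorm(config$latent_dim * B), config$latent_dim, B)
      gf <- gen_forward(par$gen, Z, Yr, config)
      Xf <- gf$X

      # ---- critic update ----
      ff <- disc_forward(par$disc, Xf, Yr, config$leak)
      fr <- disc_forward(par$disc, Xr, Yr, config$leak)
      dcl_f <- dcl_r <- NULL
      ac_term <- 0
      if (config$ac_weight > 0) {
        dcl_f <- config$ac_weight / B * (sigmoid(ff$clogits) - Yr)
        dcl_r <- config$ac_weight / B * (sigmoid(fr$clogits) - Yr)
        ac_term <- config$ac_weight *
          (bce_from_logits(ff$clogits, Yr) + bce_from_logits(fr$clogits, Yr))
      }
      gb_f <- disc_backprop(par$disc, Xf, Yr, ff, rep(1 / B, B), dcl_f, config$leak)
      gb_r <- disc_backprop(par$disc, Xr, Yr, fr, rep(-1 / B, B), dcl_r, config$leak)
      gp <- gp_and_grads(par$disc, Xr, Xf, Yr, config$gp_weight, config$leak,
                         runif(B))
      grads_d <- add_grads(add_grads(gb_f, gb_r), gp$grads)
      loss_d[step] <- mean(ff$score) - mean(fr$score) + gp$value + ac_term
      upd <- adam_step(par$disc, grads_d, st_d, config$lr_disc,
                       config$beta1, config$beta2, step)
      par$disc <- upd$par; st_d <- upd$state

      # ---- generator update ----
      Z <- matrix(rnorm(config$latent_dim * B), config$latent_dim, B)
      gf <- gen_forward(par$gen, Z, Yr, config)
      fg <- disc_forward(par$disc, gf$X, Yr, config$leak)
      dcl <- if (config$ac_weight > 0)
        config$ac_weight / B * (sigmoid(fg$clogits) - Yr) else NULL
      bp <- disc_backprop(par$disc, gf$X, Yr, fg, rep(-1 / B, B), dcl, config$leak)
      loss_g[step] <- -mean(fg$score) +
        if (config$ac_weight > 0)
          config$ac_weight * bce_from_logits(fg$clogits, Yr) else 0
      # softmax backward per 21-channel block
      dX <- bp$dX
      P <- gf$X
      dim(dX) <- dim(P) <- c(PAD_CHANNEL, config$seq_len * B)
      dlog <- P * sweep(dX, 2, colSums(P * dX), "-")
      dim(dlog) <- c(PAD_CHANNEL * config$seq_len, B)
      dH <- crossprod(par$gen$W2, dlog)
      dA <- dH * lrelu_grad(gf$A, config$leak)
      grads_g <- list(W2 = tcrossprod(dlog, gf$H), b2 = rowSums(dlog),
                      W1 = tcrossprod(dA, gf$Tm), b1 = rowSums(dA))
      upd <- adam_step(par$gen, grads_g, st_g, config$lr_gen,
                       config$beta1, config$beta2, step)
      par$gen <- upd$par; st_g <- upd$state

      if (!is.finite(loss_d[step]) || !is.finite(loss_g[step]))
        stop("training diverged (non-finite loss) at step ", step)
    }
    structure(list(params = par, config = config, vocabulary = vocab,
                   losses = list(disc = loss_d, gen = loss_g)),
              class = "cgan_model")
  })
}

#' @export
#' @method print cgan_model
print.cgan_model <- function(x, ...) {
  cat(sprintf(
    "cgan_model: L=%d, %d labels, %d steps trained (final critic loss %.3f)\n",
    x$config$seq_len, length(x$vocabulary), x$config$steps,
    tail_or_na(x$losses$disc)))
  invisible(x)
}

tail_or_na <- function(v) if (length(v)) v[length(v)] else NA_real_

#' Sample sequences from a trained conditional GAN
#'
#' Draws latent noise, conditions on the requested label sets, and decodes the
#' generator's per-position categorical output by argmax over the 21 channels;
#' the sequence is truncated at the first padding channel. Positions up to
#' `min_len` are decoded over the amino-acid channels only, so every sample
#' has at least `min_len` residues.
#'
#' @param model A `cgan_model`.
#' @param labels A character vector of term ids (one label per set) or a list
#'   of character vectors (label sets), recycled to `count`.
#' @param count Number of sequences.
#' @param seed Integer seed.
#' @param min_len Minimum decoded length (default 3, one k-mer at the default
#'   spectrum order).
#' @return A `labeled_dataset` with the conditioning labels attached.
#' @export
sample_cgan <- function(model, labels, count, seed = 1, min_len = 3) {
  if (!is.list(labels)) labels <- as.list(labels)
  labels <- rep(labels, length.out = count)
  Y <- encode_labels(labels, model$vocabulary)
  config <- model$config
  with_seed(seed, {
    Z <- matrix(rnorm(config$latent_dim * count), config$latent_dim, count)
    X <- gen_forward(model$params$gen, Z, Y, config)$X
    res <- character(count)
    for (s in seq_len(count)) {
      m <- matrix(X[, s], PAD_CHANNEL, config$seq_len)
      ch <- apply(m, 2, which.max)
      ch[seq_len(min(min_len, config$seq_len))] <-
        apply(m[-PAD_CHANNEL, seq_len(min(min_len, config$seq_len)), drop = FALSE],
              2, which.max)
      stop_at <- which(ch == PAD_CHANNEL)
      keep <- if (length(stop_at)) seq_len(stop_at[1] - 1L) else seq_along(ch)
      res[s] <- paste(AA_ALPHABET[ch[keep]], collapse = "")
    }
    labeled_dataset(sprintf("cgan%05d", seq_len(count)), res, labels,
                    vocabulary = model$vocabulary)
  })
}

#' @export
simulate.cgan_model <- function(object, nsim = 1, seed = 1, labels, ...) {
  sample_cgan(object, labels, nsim, seed = seed)
}

#' Critic score of a trained model
#'
#' `D(x, y)` for encoded inputs; columns are samples.
#'
#' @param model A `cgan_model`.
#' @param x One-hot (or relaxed) sequence matrix, `21 * seq_len` rows.
#' @param y Label encoding matrix, one column per sample.
#' @return Numeric vector of scores.
#' @export
cgan_critic_score <- function(model, x, y) {
  disc_forward(model$params$disc, as.matrix(x), as.matrix(y),
               model$config$leak)$score
}

#' Gradient-penalty term of a trained model
#'
#' Evaluates `lambda * mean((||grad_x D(xhat, y)|| - 1)^2)` on the
#' interpolates `xhat = eps * x_real + (1 - eps) * x_fake`, returning the
#' value and the per-sample input-gradient norms, so the term can be verified
#' against an independent (e.g. finite-difference) differentiation of the
#' critic.
#'
#' @param model A `cgan_model`.
#' @param x_real,x_fake Encoded sequence matrices (columns = samples).
#' @param y Label encoding matrix.
#' @param eps Interpolation coefficients in `[0, 1]`, one per sample.
#' @return List with `value` and `norms`.
#' @export
cgan_gradient_penalty <- function(model, x_real, x_fake, y, eps) {
  r <- gp_and_grads(model$params$disc, as.matrix(x_real), as.matrix(x_fake),
                    as.matrix(y), model$config$gp_weight, model$config$leak,
                    eps)
  list(value = r$value, norms = r$norms)
}

#' Generic multi-projection discriminator score
#'
#' Evaluates the conditional discriminator
#' `D(x, y) = A( sum_i ( v_i(y)' h_i(x) + g_i(x) ) )`, where branch `i` is a
#' stack of layers `l^i_1 .. l^i_{n_i}`, `h_i(x)` is the intermediate
#' representation after layer `p_i`, `v_i` a linear label projection and
#' `g_i(x)` the branch's scalar output. Branches may share prefix layers (a
#' tree-like structure) simply by being built from the same layer objects.
#' With a single branch this reduces exactly to the projection form
#' `A(v(y)' phi(x) + psi(phi(x)))`.
#'
#' @param x Numeric input vector (e.g. a flattened one-hot sequence).
#' @param y Numeric label encoding vector.
#' @param branches List of branches; each branch is a list with `layers` (a
#'   list of layers, each `list(W, b, act)` with `act` one of `"identity"`,
#'   `"lrelu"`), `p` (the projection layer index) and `V` (projection matrix,
#'   rows matching layer `p`'s output). The last layer of each branch must
#'   output a scalar.
#' @param activation Output activation `A`: a function or `"identity"`.
#' @param leak Negative slope for `"lrelu"` layers.
#' @return The scalar score.
#' @export
discriminator_score <- function(x, y, branches, activation = "identity",
                                leak = 0.2) {
  act_fun <- if (is.function(activation)) activation else identity
  total <- 0
  for (b in branches) {
    stopifnot(b$p >= 1, b$p <= length(b$layers))
    h <- x
    h_at_p <- NULL
    for (li in seq_along(b$layers)) {
      l <- b$layers[[li]]
      h <- as.numeric(l$W %*% h + l$b)
      if (identical(l$act, "lrelu")) h <- lrelu(h, leak)
      if (li == b$p) h_at_p <- h
    }
    if (length(h) != 1) stop("branch head must output a scalar")
    total <- total + sum(as.numeric(b$V %*% y) * h_at_p) + h
  }
  act_fun(total)
}

#' Auxiliary-classifier loss
#'
#' Per-label binary cross-entropy of predicted label probabilities against the
#' true multilabel encoding, summed over labels, averaged over the batch and
#' scaled by `gamma`. This is the multilabel reading of the cross-entropy
#' conditioning term: label encodings are sums of one-hot vectors, so each
#' label is scored as an independent Bernoulli.
#'
#' @param probs Matrix of predicted probabilities (labels x samples) in
#'   `[0, 1]`; values are clamped away from 0/1 by `eps` before the log.
#' @param y_true Multilabel 0/1 matrix of the same shape.
#' @param gamma Loss weight (default 1; 0 disables the term).
#' @param eps Clamping constant.
#' @return Nonnegative scalar loss.
#' @export
ac_loss <- function(probs, y_true, gamma = 1, eps = 1e-12) {
  probs <- as.matrix(probs); y_true <- as.matrix(y_true)
  stopifnot(all(dim(probs) == dim(y_true)))
  if (any(probs < 0 | probs > 1)) stop("probabilities outside [0, 1]")
  if (gamma == 0) return(0)
  p <- pmin(pmax(probs, eps), 1 - eps)
  gamma * mean(colSums(-y_true * log(p) - (1 - y_true) * log(1 - p)))
}
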