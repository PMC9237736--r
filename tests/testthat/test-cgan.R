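test_that("the projection discriminator matches hand-computed linear algebra", {
  # toy: length-2 input, all maps linear, A = identity, k = 1
  W1 <- matrix(c(1, 0, -1, 2), 2, 2)   # phi(x) = W1 x + b1
  b1 <- c(0.5, -0.5)
  w2 <- matrix(c(2, 1), 1)             # psi = w2 h + b2
  b2 <- 0.25
  V <- matrix(c(1, -1, 0, 2), 2, 2)    # v(y) = V y
  br <- list(list(layers = list(list(W = W1, b = b1, act = "identity"),
                                list(W = w2, b = b2, act = "identity")),
                  p = 1, V = V))
  x <- c(0.3, -0.7); y <- c(1, 0)
  h <- as.numeric(W1 %*% x + b1)
  manual <- sum(as.numeric(V %*% y) * h) + sum(w2 * h) + b2
  expect_equal(discriminator_score(x, y, br), manual)
  # v = 0: label-independent (projection ablation)
  br0 <- br; br0[[1]]$V <- 0 * V
  expect_equal(discriminator_score(x, y, br0),
               discriminator_score(x, c(0, 1), br0))
  # k = 2 identical branches: score doubles under identity activation
  expect_equal(discriminator_score(x, y, c(br, br)),
               2 * discriminator_score(x, y, br))
  expect_error(discriminator_score(x, y,
    list(list(layers = br[[1]]$layers, p = 3, V = V))))
})

test_that("the trained critic is the k = 1 projection discriminator", {
  ds <- flat_corpus(30, d = 2, seed = 2, length_mean = 10, length_sd = 1,
                    length_min = 8, length_max = 12)
  m <- train_cgan(ds, cgan_config(seq_len = 12, steps = 10, batch_size = 8,
                                  seed = 1))
  p <- m$params$disc
  br <- list(list(layers = list(list(W = p$W1, b = p$b1, act = "lrelu"),
                                list(W = matrix(p$w2, 1), b = p$b2,
                                     act = "identity")),
                  p = 1, V = p$V))
  set.seed(3)
  x <- runif(21 * 12); y <- c(1, 0)
  expect_equal(discriminator_score(x, y, br, leak = m$config$leak),
               as.numeric(cgan_critic_score(m, matrix(x), matrix(y))),
               tolerance = 1e-12)
})

test_that("auxiliary-classifier loss matches closed forms", {
  d <- 4; B <- 3
  y <- matrix(rbinom(d * B, 1, 0.5), d, B)
  # perfect predictions: loss -> 0
  p_perfect <- y * (1 - 1e-13) + (1 - y) * 1e-13
  expect_lt(ac_loss(p_perfect, y, gamma = 1), 1e-10)
  # probability one half everywhere: gamma * d * log(2)
  expect_equal(ac_loss(matrix(0.5, d, B), y, gamma = 2), 2 * d * log(2))
  # gamma = 0 disables the term
  expect_equal(ac_loss(matrix(0.9, d, B), y, gamma = 0), 0)
  # monotone in per-label error
  expect_gt(ac_loss(matrix(0.1, d, B), 1 + 0 * y, gamma = 1),
            ac_loss(matrix(0.4, d, B), 1 + 0 * y, gamma = 1))
  expect_error(ac_loss(matrix(1.5, d, B), y), "outside")
})

test_that("gradient penalty agrees with finite-difference input gradients", {
  ds <- flat_corpus(20, d = 2, seed = 5, length_mean = 8, length_sd = 1,
                    length_min = 6, length_max = 10)
  m <- train_cgan(ds, cgan_config(seq_len = 6, steps = 5, batch_size = 8,
                                  seed = 3))
  set.seed(7)
  B <- 3; D <- 21 * 6
  Xr <- matrix(runif(D * B), D, B); Xf <- matrix(runif(D * B), D, B)
  Y <- matrix(rbinom(2 * B, 1, 0.5), 2, B)
  eps <- runif(B)
  gp <- cgan_gradient_penalty(m, Xr, Xf, Y, eps)
  Xh <- sweep(Xr, 2, eps, "*") + sweep(Xf, 2, 1 - eps, "*")
  h <- 1e-6
  num_norms <- vapply(seq_len(B), function(b) {
    g <- vapply(seq_len(D), function(i) {
      xp <- Xh[, b]; xp[i] <- xp[i] + h
      xm <- Xh[, b]; xm[i] <- xm[i] - h
      (cgan_critic_score(m, matrix(xp), Y[, b, drop = FALSE]) -
         cgan_critic_score(m, matrix(xm), Y[, b, drop = FALSE])) / (2 * h)
    }, numeric(1))
    sqrt(sum(g^2))
  }, numeric(1))
  expect_equal(gp$norms, num_norms, tolerance = 1e-5)
  expect_equal(gp$value,
               m$config$gp_weight * mean((num_norms - 1)^2),
               tolerance = 1e-5)
})

test_that("sampling yields valid sequences of bounded length with labels echoed", {
  ds <- flat_corpus(30, d = 3, seed = 6, length_mean = 10, length_sd = 2,
                    length_min = 6, length_max = 14)
  m <- train_cgan(ds, cgan_config(seq_len = 14, steps = 5, batch_size = 8,
                                  seed = 2))  # essentially untrained: shape contract
  gen <- sample_cgan(m, c("T01", "T02", "T03"), 12, seed = 4)
  expect_equal(length(gen$ids), 12)
  expect_true(all(nchar(gen$residues) >= 3))
  expect_true(all(nchar(gen$residues) <= 14))
  expect_true(all(unlist(strsplit(gen$residues, "")) %in% aa_alphabet()))
  expect_equal(unique(unlist(gen$labels)), c("T01", "T02", "T03"))
  expect_identical(sample_cgan(m, "T01", 5, seed = 9)$residues,
                   sample_cgan(m, "T01", 5, seed = 9)$residues)
})

test_that("training traces are finite and losses recorded per step", {
  ds <- flat_corpus(40, d = 2, seed = 7, length_mean = 10, length_sd = 1,
                    length_min = 8, length_max = 12)
  m <- train_cgan(ds, cgan_config(seq_len = 12, steps = 30, batch_size = 16,
                                  seed = 5))
  expect_length(m$losses$disc, 30)
  expect_true(all(is.finite(m$losses$disc)))
  expect_true(all(is.finite(m$losses$gen)))
})
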