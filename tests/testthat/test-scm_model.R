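test_that("scalar scm-attention matches the hand computation", {
  # s=1, one token: q=k=v=ReLU(2)=2, score 4/sqrt(1)=4, ReLU 4, out 4*2=8
  X <- array(2, dim = c(1, 1, 1))
  w <- list(W_qkv = matrix(1, 1, 3), b_qkv = rep(0, 3), W_out = NULL)
  out <- scm_attention(X, w, H = 1)
  expect_equal(out[1, 1, 1], 8)
})

test_that("ReLU floor: dead q/k projections give zero output", {
  # strongly negative q/k biases push Q and K to zero, so every score is
  # zero and ReLU(0) * V contributes nothing
  s <- 4
  set.seed(1)
  w <- list(W_qkv = matrix(rnorm(s * 3 * s, sd = 0.1), s, 3 * s),
            b_qkv = c(rep(-100, 2 * s), rep(0, s)), W_out = NULL)
  X <- rand_batch3(2, 3, s, seed = 2)
  out <- scm_attention(X, w, H = 2)
  expect_true(all(out == 0))
})

test_that("causal mask blocks information flow from later positions", {
  s <- 6; P <- 5; n <- 3
  w <- rand_layer_weights(s, seed = 4)
  X <- rand_batch3(n, P, s, seed = 5)
  base_att <- scm_attention(X, w, H = 2)
  base_dec <- decoder_layer(X, w, H = 2)
  for (j in 2:P) {
    Xp <- X
    Xp[, j, ] <- Xp[, j, ] + 10 * rand_batch3(n, 1, s, seed = j)[, 1, ]
    pa <- scm_attention(Xp, w, H = 2)
    pd <- decoder_layer(Xp, w, H = 2)
    expect_equal(pa[, seq_len(j - 1), , drop = FALSE],
                 base_att[, seq_len(j - 1), , drop = FALSE])
    expect_equal(pd[, seq_len(j - 1), , drop = FALSE],
                 base_dec[, seq_len(j - 1), , drop = FALSE])
  }
})

test_that("zero weights make the decoder layer an identity map", {
  s <- 4
  w <- list(W_qkv = matrix(0, s, 3 * s), b_qkv = rep(0, 3 * s),
            W_out = matrix(0, s, s),
            g1 = rep(0, s), be1 = rep(0, s), g2 = rep(0, s),
            be2 = rep(0, s),
            W1 = matrix(0, s, 2 * s), b1 = rep(0, 2 * s),
            W2 = matrix(0, 2 * s, s), b2 = rep(0, s))
  X <- rand_batch3(2, 3, s, seed = 6)
  expect_equal(decoder_layer(X, w, H = 1), X)
})

test_that("decoder layer matches the straight-line oracle on random fixtures", {
  set.seed(100)
  for (rep in 1:10) {
    n <- sample(1:4, 1); P <- sample(2:5, 1)
    H <- sample(c(1L, 2L), 1); s <- H * sample(1:4, 1)
    w <- rand_layer_weights(s, seed = 100 + rep)
    X <- rand_batch3(n, P, s, seed = 200 + rep)
    got <- decoder_layer(X, w, H = H)
    want <- oracle_decoder_layer(X, w, H = H)
    expect_equal(got, want, tolerance = 1e-5)
    got_a <- scm_attention(X, w, H = H)
    want_a <- oracle_scm_attention(X, w$W_qkv, w$b_qkv, w$W_out, H)
    expect_equal(got_a, want_a, tolerance = 1e-5)
  }
})

test_that("stacked layers compose", {
  s <- 4
  w1 <- rand_layer_weights(s, seed = 7)
  w2 <- rand_layer_weights(s, seed = 8)
  X <- rand_batch3(2, 3, s, seed = 9)
  expect_equal(decoder_layer(decoder_layer(X, w1, H = 2), w2, H = 2),
               Reduce(function(x, w) decoder_layer(x, w, H = 2),
                      list(w1, w2), accumulate = FALSE, init = X))
})

test_that("pool_latent averages per modality slice", {
  X <- array(3, dim = c(2, 4, 5))
  out <- pool_latent(X, list(a = 1:2, b = 3:4))
  expect_equal(out$a, matrix(3, 2, 5))
  # single modality covering all positions equals the global mean
  Xr <- rand_batch3(3, 4, 5, seed = 10)
  g <- pool_latent(Xr, list(all = 1:4))$all
  want <- apply(Xr, c(1, 3), mean)
  expect_equal(g, want)
  # explicit-summation oracle on a random split
  sp <- list(a = 1:3, b = 4L)
  got <- pool_latent(Xr, sp)
  for (m in names(sp)) {
    o <- matrix(0, 3, 5)
    for (i in 1:3) for (k in 1:5) {
      o[i, k] <- sum(Xr[i, sp[[m]], k]) / length(sp[[m]])
    }
    expect_equal(got[[m]], o)
  }
  expect_error(pool_latent(Xr, list(a = 1:3)), "partition")
})

test_that("reconstruct is a plain affine map", {
  set.seed(11)
  head <- list(W = matrix(rnorm(12), 3, 4), b = rnorm(4))
  z <- matrix(0, 2, 3)
  expect_equal(reconstruct(z, head), rbind(head$b, head$b),
               ignore_attr = TRUE)
  id_head <- list(W = diag(3), b = rep(0, 3))
  L <- matrix(rnorm(6), 2, 3)
  expect_equal(reconstruct(L, id_head), L)
  # hand multiply on a 2x3 latent
  want <- L %*% head$W + rep(head$b, each = 2)
  expect_equal(reconstruct(L, head), want)
  expect_error(reconstruct(matrix(0, 2, 5), head), "width")
})

test_that("forward pass is cell-permutation equivariant and deterministic", {
  cfg <- tiny_cfg(seed = 12)
  set.seed(cfg$seed)
  model <- init_model(cfg, 8L, 2L, head_dims = c(rna = 16L, protein = 16L))
  Xmats <- list(rna = matrix(rnorm(5 * 16), 5, 16),
                protein = matrix(rnorm(5 * 16), 5, 16))
  fw <- scmformer:::model_forward(model, Xmats)
  perm <- c(3, 1, 5, 2, 4)
  fwp <- scmformer:::model_forward(
    model, lapply(Xmats, function(x) x[perm, ]))
  expect_equal(fwp$latents$rna, fw$latents$rna[perm, ],
               ignore_attr = TRUE)
  expect_equal(fwp$recon$protein, fw$recon$protein[perm, ],
               ignore_attr = TRUE)
  # repeated evaluation is bitwise identical
  expect_identical(fw$latents,
                   scmformer:::model_forward(model, Xmats)$latents)
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg(s = 4, H = 2, n_layers = 2, seed = 13, aligned_dim = 8)
  set.seed(cfg$seed)
  n <- 3
  Xmats <- list(rna = matrix(rnorm(n * 8), n, 8),
                protein = matrix(rnorm(n * 8), n, 8))
  model <- init_model(cfg, 4L, 2L, head_dims = c(rna = 8L, protein = 8L))

  loss_of <- function(m) {
    fw <- scmformer:::model_forward(m, Xmats, keep_cache = TRUE)
    rec <- vapply(names(Xmats),
                  function(k) loss_rec(fw$recon[[k]], Xmats[[k]]), 1)
    list(loss = loss_integration(rec, loss_comb(fw$latents),
                                 cfg$lambda_rec), fw = fw)
  }
  r <- loss_of(model)
  dRecon <- lapply(names(Xmats), function(k) {
    cfg$lambda_rec * 2 * (r$fw$recon[[k]] - Xmats[[k]]) /
      length(Xmats[[k]])
  })
  names(dRecon) <- names(Xmats)
  dd <- r$fw$latents$rna - r$fw$latents$protein
  dLat <- list(rna = 2 * dd / length(dd), protein = -2 * dd / length(dd))
  grads <- scmformer:::model_backward(model, r$fw, dLatents = dLat,
                                      dRecon = dRecon)

  poke <- function(w, path, idx, h) {
    if (length(path) == 1) {
      w[[path[[1]]]][idx] <- w[[path[[1]]]][idx] + h
      return(w)
    }
    w[[path[[1]]]] <- poke(w[[path[[1]]]], path[-1], idx, h)
    w
  }
  fetch <- function(w, path) {
    if (length(path) == 1) w[[path[[1]]]] else fetch(w[[path[[1]]]],
                                                    path[-1])
  }
  paths <- list(list("pos"), list("mod"),
                list("layers", 1L, "W_qkv"), list("layers", 1L, "W_out"),
                list("layers", 1L, "g1"), list("layers", 1L, "W1"),
                list("layers", 2L, "W_qkv"), list("layers", 2L, "b2"),
                list("heads", "rna", "W"), list("heads", "protein", "b"))
  set.seed(14)
  for (p in paths) {
    g_arr <- fetch(grads, p); w_arr <- fetch(model$weights, p)
    for (idx in sample(length(w_arr), min(4, length(w_arr)))) {
      h <- 1e-5
      mp <- model; mp$weights <- poke(model$weights, p, idx, h)
      mm <- model; mm$weights <- poke(model$weights, p, idx, -h)
      num <- (loss_of(mp)$loss - loss_of(mm)$loss) / (2 * h)
      expect_equal(g_arr[idx], num, tolerance = 1e-4)
    }
  }
})
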