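test_that("loss algebra obeys the stated limits", {
  A <- matrix(1:6 / 3, 2, 3)
  expect_identical(loss_rec(A, A), 0)
  expect_identical(loss_rec(A + 1, A), 1)
  # element-loop oracle on a random fixture
  set.seed(1)
  P <- matrix(rnorm(12), 3, 4); Q <- matrix(rnorm(12), 3, 4)
  acc <- 0
  for (i in 1:3) for (j in 1:4) acc <- acc + (P[i, j] - Q[i, j])^2
  expect_equal(loss_rec(P, Q), acc / 12)
  expect_error(loss_rec(P, matrix(0, 2, 2)), "shape")

  expect_identical(loss_comb(list(A, A)), 0)
  expect_identical(loss_comb(list(A, A, A)), 0)      # pairwise extension
  expect_identical(loss_comb(list(A, A + 2)), 4)     # squared constant
  expect_error(loss_comb(list(A)), "at least two")
  expect_error(loss_comb(list(A, matrix(0, 3, 3))), "unpaired")

  expect_identical(loss_integration(c(0.3, 0.2), 0.7, 0), 0.7)
  expect_identical(loss_integration(c(0.3, 0.2), 0, 2), 1)
  expect_identical(loss_integration(0.1, 0.5, 70), 7.5)
  expect_error(loss_integration(0.1, 0.5, -1), "lambda")
})

test_that("losses are invariant to a shared cell permutation", {
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5); Y <- matrix(rnorm(40), 8, 5)
  R <- matrix(rnorm(40), 8, 5)
  perm <- sample(8)
  expect_equal(loss_rec(R, X), loss_rec(R[perm, ], X[perm, ]))
  expect_equal(loss_comb(list(X, Y)), loss_comb(list(X[perm, ], Y[perm, ])))
})

test_that("integration training reduces the loss and is seed-deterministic", {
  ds <- tiny_reduced_pair(n = 60, D = 16, seed = 21)
  cfg <- tiny_cfg(epochs = 4, batch_size = 16, seed = 5, drop_rate = 0.1)
  m1 <- train_integration(ds, cfg)
  expect_identical(nrow(m1$trace), 4L)
  expect_lt(m1$trace$loss[4], m1$trace$loss[1])
  m2 <- train_integration(ds, cfg)
  expect_identical(m1$trace, m2$trace)             # bitwise determinism
  expect_identical(m1$weights, m2$weights)

  bad <- tiny_reduced_pair(n = 20, D = 15, seed = 3)
  expect_error(train_integration(bad, cfg), "divisible")
  one <- structure(list(modalities = ds$modalities[1],
                        pairing = "by_order", labels = NULL),
                   class = "paired_dataset")
  expect_error(train_integration(one, cfg), ">= 2 modalities")
})

test_that("extract_latents is deterministic, width-s, input-functional", {
  ds <- tiny_reduced_pair(n = 30, D = 16, seed = 22)
  cfg <- tiny_cfg(epochs = 2, seed = 6, drop_rate = 0.2)
  model <- train_integration(ds, cfg)
  l1 <- extract_latents(model, ds)
  l2 <- extract_latents(model, ds, batch_size = 7)   # chunking irrelevant
  expect_identical(lapply(l1, `[[`, "values"), lapply(l2, `[[`, "values"))
  expect_identical(ncol(l1$rna$values), cfg$s)
  # duplicated cells produce identical latent rows
  dsd <- structure(list(modalities = lapply(ds$modalities, function(m) {
    modality_matrix(m$values[c(1, 1, 2), ], c("d1", "d2", "d3"),
                    m$feature_ids, m$modality, m$layer)
  }), pairing = "by_order", labels = NULL), class = "paired_dataset")
  ld <- extract_latents(model, dsd)
  expect_equal(ld$rna$values[1, ], ld$rna$values[2, ], ignore_attr = TRUE)
})

test_that("generation recovers a noiseless linear map and beats the mean baseline", {
  # shared latent, exactly linear observations
  set.seed(31)
  n <- 240; latent_dim <- 4; D <- 16; v <- 10
  L <- matrix(rnorm(n * latent_dim), n, latent_dim)
  A <- matrix(rnorm(latent_dim * D), latent_dim, D)
  B <- matrix(rnorm(latent_dim * v), latent_dim, v)
  X <- L %*% A
  Y <- L %*% B
  tr <- 1:200; te <- 201:240
  src <- modality_matrix(X[tr, ], paste0("c", tr), paste0("x", 1:D),
                         "rna", "reduced")
  tgt <- modality_matrix(Y[tr, ], paste0("c", tr), paste0("y", 1:v),
                         "protein", "normalized")
  cfg <- tiny_cfg(epochs = 150, batch_size = 32, seed = 7)
  model <- train_generation(src, tgt, cfg)
  pred <- generate(model, X[te, ])
  expect_identical(dim(pred), c(40L, 10L))
  mse <- mean((pred - Y[te, ])^2)
  expect_lt(mse, 0.1 * var(as.vector(Y[te, ])))
  gs <- generation_scores(pred, Y[te, ])
  base <- matrix(colMeans(Y[tr, ]), 40, v, byrow = TRUE)
  gb <- generation_scores(base, Y[te, ])
  expect_gt(mean(gs$pearson_per_feature), mean(gb$pearson_per_feature))
})

test_that("generate is deterministic, order-preserving, and guards shapes", {
  ds <- tiny_reduced_pair(n = 40, D = 16, seed = 23)
  src <- ds$modalities$rna
  tgt <- modality_matrix(ds$modalities$protein$values[, 1:5],
                         ds$modalities$protein$cell_ids,
                         paste0("p", 1:5), "protein", "normalized")
  cfg <- tiny_cfg(epochs = 3, seed = 8, drop_rate = 0.1)
  model <- train_generation(src, tgt, cfg)
  p1 <- generate(model, src)
  expect_identical(colnames(p1), paste0("p", 1:5))
  p2 <- generate(model, src)
  expect_identical(p1, p2)
  # row order follows the input
  p3 <- generate(model, src$values[c(3, 1), ])
  expect_equal(p3[1, ], p1[3, ], ignore_attr = TRUE)
  expect_equal(p3[2, ], p1[1, ], ignore_attr = TRUE)
  # an all-zero cell yields a finite intercept response
  pz <- generate(model, matrix(0, 1, 16))
  expect_true(all(is.finite(pz)))
  expect_error(generate(model, matrix(0, 2, 12)), "width")
  expect_error(generate(train_integration(ds, tiny_cfg(epochs = 1,
                                                       seed = 1)),
                        src), "train_generation")
})
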