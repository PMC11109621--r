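test_that("normalize_rna matches the closed form and handles zero cells", {
  m <- modality_matrix(rbind(c(1, 1, 2), c(0, 0, 0), c(2, 2, 4)),
                       paste0("c", 1:3), paste0("g", 1:3), "rna", "raw")
  cfg <- preprocess_config(target_sum = 4)
  expect_warning(out <- normalize_rna(m, cfg), "zero total")
  expect_equal(out$values[1, ], c(g1 = log(2), g2 = log(2), g3 = log(3)))
  expect_equal(out$values[2, ], c(g1 = 0, g2 = 0, g3 = 0))
  # proportional cells normalize identically (scale invariance)
  expect_equal(out$values[1, ], out$values[3, ])
  expect_identical(out$layer, "normalized")
})

test_that("CLR rows are centered and match the closed form", {
  cfg <- preprocess_config(clr_pseudocount = 1)
  m <- modality_matrix(rbind(c(5, 5, 5), c(0, exp(1) - 1, 0)),
                       c("a", "b"), paste0("p", 1:3), "protein", "raw")
  out <- normalize_protein(m, cfg)
  expect_equal(unname(out$values[1, ]), c(0, 0, 0))
  # row (0, e-1) with c=1: log values (0, 1) centered -> (-.5, +.5)
  m2 <- modality_matrix(matrix(c(0, exp(1) - 1), 1, 2), "a", c("p1", "p2"),
                        "protein", "raw")
  out2 <- normalize_protein(m2, cfg)
  expect_equal(unname(out2$values[1, ]), c(-0.5, 0.5))
  # centering identity on random counts
  r <- rand_mm(20, 7, "protein", seed = 4)
  expect_lt(max(abs(rowSums(normalize_protein(r, cfg)$values))), 1e-9)
  neg <- modality_matrix(matrix(c(-1, 2), 1, 2), "a", c("p1", "p2"),
                         "protein", "raw")
  expect_error(normalize_protein(neg, cfg), "non-negative")
})

test_that("normalize_rna is invariant to per-cell count rescaling", {
  m <- rand_mm(10, 20, seed = 6)
  scaled <- modality_matrix(m$values * (1:10), m$cell_ids, m$feature_ids,
                            "rna", "raw")
  expect_equal(normalize_rna(m)$values, normalize_rna(scaled)$values,
               tolerance = 1e-12)
})

test_that("select_hvg keeps top dispersion features in original order", {
  m <- rand_mm(10, 10, seed = 1, layer = "raw")
  norm <- normalize_rna(m)
  expect_identical(select_hvg(norm, 10), norm)          # identity case
  expect_error(select_hvg(norm, 1), "n_hvg")

  # a dominant-variance feature at comparable mean is always kept
  set.seed(2)
  base <- matrix(rnorm(40 * 6, mean = 10, sd = 0.5), 40, 6)
  base[, 4] <- 10 + rnorm(40, sd = 5)
  md <- modality_matrix(base, paste0("c", 1:40), paste0("g", 1:6),
                        "rna", "normalized")
  kept <- select_hvg(md, 2)
  expect_true("g4" %in% kept$feature_ids)

  # ranking equals an independent re-computation of the binned dispersion
  set.seed(3)
  x <- matrix(abs(rnorm(5 * 6)), 5, 6)
  mm <- modality_matrix(x, paste0("c", 1:5), paste0("g", 1:6),
                        "rna", "normalized")
  mu <- colMeans(x); v <- apply(x, 2, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- 3  # floor(6/2) limits the bins
  br <- unique(quantile(mu, seq(0, 1, length.out = nb + 1)))
  bins <- cut(mu, br, include.lowest = TRUE)
  z <- ave(disp, bins, FUN = function(d) {
    if (length(d) < 2 || sd(d) == 0) rep(0, length(d)) else
      (d - mean(d)) / sd(d)
  })
  want <- sort(head(order(z, decreasing = TRUE), 3))
  got <- match(select_hvg(mm, 3)$feature_ids, mm$feature_ids)
  expect_identical(got, want)
})

test_that("align_dims reduces, pads, and matches the eigen oracle", {
  set.seed(9)
  n <- 50
  X <- matrix(rnorm(n * 20), n, 20) %*% diag(seq(3, 0.5, length.out = 20))
  Yp <- matrix(rnorm(n * 6), n, 6)
  ds <- pair(list(
    modality_matrix(X, paste0("c", 1:n), paste0("g", 1:20), "rna",
                    "normalized"),
    modality_matrix(Yp, paste0("c", 1:n), paste0("p", 1:6), "protein",
                    "normalized")), "by_order")
  red <- align_dims(ds, 8, scale_total_var = FALSE)
  expect_identical(ncol(red$modalities$rna$values), 8L)
  # small panel zero-padded, original values untouched
  expect_identical(red$modalities$protein$values[, 1:6], Yp,
                   ignore_attr = TRUE)
  expect_true(all(red$modalities$protein$values[, 7:8] == 0))

  # PCA scores match the eigendecomposition oracle up to column sign
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  oracle <- Xc %*% eig$vectors[, 1:8]
  got <- red$modalities$rna$values
  for (j in 1:8) {
    sgn <- sign(sum(oracle[, j] * got[, j]))
    expect_equal(got[, j], sgn * oracle[, j], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # kept-component variance dominates any discarded component
  vars <- apply(got, 2, var)
  expect_gte(min(vars), eig$values[9] - 1e-8)

  # PCA rank limit: more requested dimensions than cells
  tiny <- pair(list(
    modality_matrix(matrix(rnorm(10 * 20), 10, 20), paste0("c", 1:10),
                    paste0("g", 1:20), "rna", "normalized"),
    modality_matrix(matrix(rnorm(10 * 20), 10, 20), paste0("c", 1:10),
                    paste0("h", 1:20), "protein", "normalized")),
    "by_order")
  expect_error(align_dims(tiny, 15), "rank insufficient")
})

test_that("align_dims with exactly aligned_dim features takes the PCA branch", {
  set.seed(10)
  X <- matrix(rnorm(30 * 8), 30, 8)
  ds <- pair(list(
    modality_matrix(X, paste0("c", 1:30), paste0("g", 1:8), "rna",
                    "normalized"),
    modality_matrix(X, paste0("c", 1:30), paste0("h", 1:8), "protein",
                    "normalized")), "by_order")
  red <- align_dims(ds, 8, scale_total_var = FALSE)
  expect_identical(ncol(red$modalities$rna$values), 8L)
  # PCA output is centered; padding would have left the raw values
  expect_lt(max(abs(colMeans(red$modalities$rna$values))), 1e-10)
})

test_that("fitted preprocessor replays identically on training data", {
  sim <- simulate_paired(sim_config(n_cells = 60, n_genes = 50,
                                    n_proteins = 12, seed = 2))
  pcfg <- preprocess_config(n_hvg = 40, aligned_dim = 8)
  m <- sim$dataset$modalities$rna
  pp <- fit_preprocessor(m, pcfg)
  red <- apply_preprocessor(pp, m)
  expect_identical(dim(red$values), c(60L, 8L))
  expect_identical(red$layer, "reduced")
  # applying twice gives the same result (deterministic transform)
  expect_identical(apply_preprocessor(pp, m)$values, red$values)
  # query with permuted feature columns maps through the stored feature set
  perm <- sample(ncol(m$values))
  mq <- modality_matrix(m$values[, perm], m$cell_ids,
                        m$feature_ids[perm], "rna", "raw")
  expect_equal(apply_preprocessor(pp, mq)$values, red$values,
               tolerance = 1e-12)
})
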