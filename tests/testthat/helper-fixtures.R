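# shared fixture builders; everything is generated in code, no files

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(s = 4, H = 2, n_layers = 1, drop_rate = 0,
                   lambda_rec = 2, lr = 3e-3, batch_size = 8, epochs = 3,
                   seed = 1, aligned_dim = 16, n_hvg = 10)
  do.call(scm_config, utils::modifyList(defaults, args))
}

rand_mm <- function(n = 4, p = 5, modality = "rna", layer = "raw",
                    seed = 1, counts = TRUE) {
  set.seed(seed)
  v <- if (counts) matrix(rpois(n * p, 5), n, p) else matrix(rnorm(n * p), n, p)
  modality_matrix(v, paste0("c", seq_len(n)), paste0("f", seq_len(p)),
                  modality = modality, layer = layer)
}

sub_mm <- function(m, idx) {
  modality_matrix(m$values[idx, , drop = FALSE], m$cell_ids[idx],
                  m$feature_ids, m$modality, m$layer)
}

rand_batch3 <- function(n, P, s, seed = 1) {
  set.seed(seed)
  array(rnorm(n * P * s), dim = c(n, P, s))
}

rand_layer_weights <- function(s, seed = 1) {
  set.seed(seed)
  list(W_qkv = matrix(rnorm(s * 3 * s, sd = 0.4), s, 3 * s),
       b_qkv = rnorm(3 * s, sd = 0.1),
       W_out = matrix(rnorm(s * s, sd = 0.4), s, s),
       g1 = runif(s, 0.5, 1.5), be1 = rnorm(s, sd = 0.1),
       g2 = runif(s, 0.5, 1.5), be2 = rnorm(s, sd = 0.1),
       W1 = matrix(rnorm(s * 2 * s, sd = 0.4), s, 2 * s),
       b1 = rnorm(2 * s, sd = 0.1),
       W2 = matrix(rnorm(2 * s * s, sd = 0.4), 2 * s, s),
       b2 = rnorm(s, sd = 0.1))
}

# small reduced paired dataset with a shared latent signal, for fast
# training tests
tiny_reduced_pair <- function(n = 80, D = 16, latent_dim = 4, seed = 7,
                              noise = 0.1, labels = TRUE) {
  set.seed(seed)
  types <- sample(2, n, replace = TRUE)
  ctr <- matrix(rnorm(2 * latent_dim, sd = 2), 2, latent_dim)
  L <- ctr[types, ] + matrix(rnorm(n * latent_dim, sd = 0.3), n, latent_dim)
  A <- matrix(rnorm(latent_dim * D), latent_dim, D)
  B <- matrix(rnorm(latent_dim * D), latent_dim, D)
  X <- L %*% A + matrix(rnorm(n * D, sd = noise), n, D)
  Y <- L %*% B + matrix(rnorm(n * D, sd = noise), n, D)
  ids <- paste0("c", seq_len(n))
  ds <- pair(list(
    modality_matrix(X, ids, paste0("x", 1:D), "rna", "reduced"),
    modality_matrix(Y, ids, paste0("y", 1:D), "protein", "reduced")),
    "by_order", labels = if (labels) paste0("t", types) else NULL)
  ds
}
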