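# Seeded generator of paired multimodal data with the structure the model
# assumes: every cell has one shared latent state (cluster centroid plus
# within-type jitter) observed twice, through an RNA-like count channel
# (log-linear rates, Poisson noise, Bernoulli dropout) and a protein-like
# abundance channel (log-linear rates, additive noise, rounding,
# non-negativity).  Defaults describe a small but realistic desk-scale
# world: 600 cells, 3 types, 400 genes, 40 proteins; see the methods
# vignette for the reasoning behind each noise level.

#' Simulation configuration
#'
#' @param n_cells Number of paired cells.
#' @param n_types Number of cell types (latent clusters).
#' @param n_genes RNA features.
#' @param n_proteins Protein features.
#' @param latent_dim Dimension of the shared per-cell latent state.
#' @param noise_sd_rna Extra Gaussian noise sd on the RNA log-rate (on top
#'   of Poisson sampling noise).
#' @param noise_sd_protein Additive Gaussian noise sd on the protein count
#'   scale, applied before rounding.
#' @param batch_shift_sd Sd of an optional per-batch mean shift on the
#'   log-rates (`0` = single batch).
#' @param n_batches Number of batches when `batch_shift_sd > 0`.
#' @param dropout_rate_rna Bernoulli zeroing probability for RNA counts.
#' @param within_type_sd Latent jitter sd around each type centroid.
#' @param count_noise If `FALSE`, skip Poisson sampling / rounding /
#'   dropout and emit the expected (rate-scale) values, so the counterpart
#'   modality is exactly recoverable through the known log-linear map;
#'   used to test recovery properties.
#' @param seed RNG seed; all outputs are a deterministic function of it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 600, n_types = 3, n_genes = 400,
                       n_proteins = 40, latent_dim = 10,
                       noise_sd_rna = 0.2, noise_sd_protein = 2,
                       batch_shift_sd = 0, n_batches = 1,
                       dropout_rate_rna = 0.2, within_type_sd = 0.3,
                       count_noise = TRUE, seed = 0) {
  if (n_types < 1) stop("n_types must be >= 1")
  if (dropout_rate_rna < 0 || dropout_rate_rna >= 1) {
    stop("dropout_rate_rna must be in [0, 1)")
  }
  if (noise_sd_rna < 0 || noise_sd_protein < 0 || batch_shift_sd < 0 ||
      within_type_sd < 0) {
    stop("noise sds must be >= 0")
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_types = as.integer(n_types),
                 n_genes = as.integer(n_genes),
                 n_proteins = as.integer(n_proteins),
                 latent_dim = as.integer(latent_dim),
                 noise_sd_rna = noise_sd_rna,
                 noise_sd_protein = noise_sd_protein,
                 batch_shift_sd = batch_shift_sd,
                 n_batches = as.integer(n_batches),
                 dropout_rate_rna = dropout_rate_rna,
                 within_type_sd = within_type_sd,
                 count_noise = isTRUE(count_noise),
                 seed = as.integer(seed)),
            class = "sim_config")
}

draw_world <- function(cfg) {
  # type centroids and modality loadings define the "biology"; drawn once
  list(
    centroids = matrix(stats::rnorm(cfg$n_types * cfg$latent_dim),
                       cfg$n_types, cfg$latent_dim),
    loadings_rna = matrix(stats::rnorm(cfg$latent_dim * cfg$n_genes,
                                       sd = 1 / sqrt(cfg$latent_dim)),
                          cfg$latent_dim, cfg$n_genes),
    loadings_protein = matrix(stats::rnorm(cfg$latent_dim * cfg$n_proteins,
                                           sd = 1 / sqrt(cfg$latent_dim)),
                              cfg$latent_dim, cfg$n_proteins),
    base_rna = stats::rnorm(cfg$n_genes, mean = 1, sd = 0.5),
    base_protein = stats::rnorm(cfg$n_proteins, mean = 3, sd = 0.5)
  )
}

draw_cells <- function(cfg, world, n, id_prefix = "cell",
                       type_probs = NULL) {
  types <- sample.int(cfg$n_types, n, replace = TRUE, prob = type_probs)
  latent <- world$centroids[types, , drop = FALSE] +
    matrix(stats::rnorm(n * cfg$latent_dim, sd = cfg$within_type_sd),
           n, cfg$latent_dim)
  size_offset <- stats::rnorm(n, sd = 0.3)     # cell-size (library) factor
  batch <- if (cfg$batch_shift_sd > 0 && cfg$n_batches > 1) {
    sample.int(cfg$n_batches, n, replace = TRUE)
  } else {
    rep(1L, n)
  }
  shift_rna <- matrix(0, cfg$n_batches, cfg$n_genes)
  shift_prot <- matrix(0, cfg$n_batches, cfg$n_proteins)
  if (cfg$batch_shift_sd > 0 && cfg$n_batches > 1) {
    shift_rna <- matrix(stats::rnorm(cfg$n_batches * cfg$n_genes,
                                     sd = cfg$batch_shift_sd),
                        cfg$n_batches, cfg$n_genes)
    shift_prot <- matrix(stats::rnorm(cfg$n_batches * cfg$n_proteins,
                                      sd = cfg$batch_shift_sd),
                         cfg$n_batches, cfg$n_proteins)
  }
  log_rate_rna <- sweep(latent %*% world$loadings_rna, 2, world$base_rna,
                        `+`) + size_offset + shift_rna[batch, , drop = FALSE]
  if (cfg$noise_sd_rna > 0) {
    log_rate_rna <- log_rate_rna +
      matrix(stats::rnorm(n * cfg$n_genes, sd = cfg$noise_sd_rna),
             n, cfg$n_genes)
  }
  if (cfg$count_noise) {
    rna <- matrix(stats::rpois(n * cfg$n_genes, exp(log_rate_rna)),
                  n, cfg$n_genes)
    if (cfg$dropout_rate_rna > 0) {
      keep <- matrix(stats::runif(n * cfg$n_genes) >= cfg$dropout_rate_rna,
                     n, cfg$n_genes)
      rna <- rna * keep
    }
  } else {
    rna <- exp(log_rate_rna)
  }
  prot_rate <- exp(sweep(latent %*% world$loadings_protein, 2,
                         world$base_protein, `+`) +
                   shift_prot[batch, , drop = FALSE])
  if (cfg$noise_sd_protein > 0) {
    prot_rate <- prot_rate +
      matrix(stats::rnorm(n * cfg$n_proteins, sd = cfg$noise_sd_protein),
             n, cfg$n_proteins)
  }
  protein <- if (cfg$count_noise) pmax(round(prot_rate), 0) else prot_rate
  ids <- sprintf("%s_%0*d", id_prefix, nchar(n) + 1, seq_len(n))
  list(types = paste0("type_", types), latent = latent, rna = rna,
       protein = protein, batch = batch, ids = ids)
}

#' Simulate a paired RNA + protein dataset
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a raw-layer [pair()]ed dataset with
#'   labels) and `truth` (class `sim_truth`: per-cell types, shared latent
#'   states, the world of centroids/loadings, and the configuration).
#' @export
simulate_paired <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  world <- draw_world(cfg)
  if (cfg$n_cells == 0) {
    rna <- modality_matrix(matrix(0, 0, cfg$n_genes), character(0),
                           paste0("gene_", seq_len(cfg$n_genes)),
                           modality = "rna", layer = "raw")
    prot <- modality_matrix(matrix(0, 0, cfg$n_proteins), character(0),
                            paste0("prot_", seq_len(cfg$n_proteins)),
                            modality = "protein", layer = "raw")
    ds <- pair(list(rna, prot), "by_order", labels = character(0))
    truth <- structure(list(cell_types = character(0),
                            latent_states = matrix(0, 0, cfg$latent_dim),
                            world = world, config = cfg),
                       class = "sim_truth")
    return(list(dataset = ds, truth = truth))
  }
  cells <- draw_cells(cfg, world, cfg$n_cells)
  rna <- modality_matrix(cells$rna, cells$ids,
                         paste0("gene_", seq_len(cfg$n_genes)),
                         modality = "rna", layer = "raw")
  prot <- modality_matrix(cells$protein, cells$ids,
                          paste0("prot_", seq_len(cfg$n_proteins)),
                          modality = "protein", layer = "raw")
  ds <- pair(list(rna, prot), "by_order", labels = cells$types)
  truth <- structure(list(cell_types = cells$types,
                          latent_states = cells$latent,
                          batch = cells$batch,
                          world = world, config = cfg),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate unpaired query cells from an existing world
#'
#' New cells are drawn from the same type centroids and loadings as an
#' existing simulation; one modality is returned as the query while the
#' held-out counterpart and labels are stored as ground truth.
#'
#' @param truth A `sim_truth` from [simulate_paired()].
#' @param n_query Number of query cells (>= 1).
#' @param modality Which modality to expose (`"rna"` or `"protein"`).
#' @param type_probs Optional cell-type sampling probabilities for the
#'   query (length `n_types`); defaults to uniform.
#' @param seed Seed for the query draw (defaults to `config seed + 1`).
#' @return List with `query` (raw-layer [modality_matrix()]), `labels`,
#'   `counterpart` (the held-out modality matrix) and `latent_states`.
#' @export
simulate_unpaired_query <- function(truth, n_query,
                                    modality = c("rna", "protein"),
                                    type_probs = NULL, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  modality <- match.arg(modality)
  if (n_query < 1) stop("n_query must be >= 1")
  cfg <- truth$config
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(seed)
  cells <- draw_cells(cfg, truth$world, as.integer(n_query),
                      id_prefix = "query", type_probs = type_probs)
  qm <- if (modality == "rna") cells$rna else cells$protein
  cm <- if (modality == "rna") cells$protein else cells$rna
  qf <- if (modality == "rna") paste0("gene_", seq_len(cfg$n_genes))
        else paste0("prot_", seq_len(cfg$n_proteins))
  cf <- if (modality == "rna") paste0("prot_", seq_len(cfg$n_proteins))
        else paste0("gene_", seq_len(cfg$n_genes))
  cmod <- if (modality == "rna") "protein" else "rna"
  list(query = modality_matrix(qm, cells$ids, qf, modality = modality,
                               layer = "raw"),
       labels = cells$types,
       counterpart = modality_matrix(cm, cells$ids, cf, modality = cmod,
                                     layer = "raw"),
       latent_states = cells$latent)
}
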