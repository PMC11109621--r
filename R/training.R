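# Multi-task objectives and the two training regimes:
#   integration  — joint sequence over all paired modalities, loss
#                  lambda * sum_m MSE(recon_m, input_m) + fusion MSE
#                  between per-modality pooled latents;
#   generation   — source-only sequence, pooled latent mapped by a linear
#                  head onto the measured target modality, plain MSE.
# Optimiser: Adam at a fixed learning rate, no schedule.

#' Reconstruction loss (mean squared error)
#'
#' @param x_rec,x Numeric matrices of identical shape.
#' @return Scalar MSE over all entries.
#' @export
loss_rec <- function(x_rec, x) {
  if (!identical(dim(x_rec), dim(x))) stop("shape mismatch in loss_rec")
  mean((x_rec - x)^2)
}

#' Fusion loss between per-modality latents
#'
#' MSE between the two latents; with three or more modalities, the mean of
#' the MSE over all unordered pairs, so the triple-omics case is handled in
#' a single objective.
#'
#' @param latents List (length >= 2) of `n x s` matrices (or
#'   `latent_representation` objects), row-paired cells.
#' @return Scalar fusion loss.
#' @export
loss_comb <- function(latents) {
  mats <- lapply(latents, function(l) {
    if (inherits(l, "latent_representation")) l$values else as.matrix(l)
  })
  if (length(mats) < 2) stop("loss_comb needs at least two latents")
  d <- dim(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), d)) stop("unpaired latent shapes in loss_comb")
  }
  pairs <- utils::combn(length(mats), 2)
  mean(apply(pairs, 2, function(p) mean((mats[[p[1]]] - mats[[p[2]]])^2)))
}

#' Integration objective
#'
#' `lambda * sum(rec_losses) + comb`.
#'
#' @param rec_losses Numeric vector of per-modality reconstruction losses.
#' @param comb Scalar fusion loss.
#' @param lambda Non-negative reconstruction weight.
#' @return Scalar total loss.
#' @export
loss_integration <- function(rec_losses, comb, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  lambda * sum(rec_losses) + comb
}

# ---- Adam -------------------------------------------------------------------

zeros_like <- function(w) {
  if (is.list(w)) return(lapply(w, zeros_like))
  w * 0
}

adam_init <- function(weights) {
  list(m = zeros_like(weights), v = zeros_like(weights), t = 0L)
}

adam_update_node <- function(w, g, m, v, lr_t, beta1, beta2, eps) {
  if (is.list(w)) {
    for (k in seq_along(w)) {
      res <- adam_update_node(w[[k]], g[[k]], m[[k]], v[[k]],
                              lr_t, beta1, beta2, eps)
      w[[k]] <- res$w; m[[k]] <- res$m; v[[k]] <- res$v
    }
    return(list(w = w, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  list(w = w - lr_t * m / (sqrt(v) + eps), m = m, v = v)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  res <- adam_update_node(weights, grads, state$m, state$v,
                          lr_t, beta1, beta2, eps)
  list(weights = res$w, state = list(m = res$m, v = res$v, t = state$t))
}

# ---- latent container -------------------------------------------------------

#' @export
latent_representation <- function(values, modality, cell_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (!all(is.finite(values))) stop("non-finite latent values")
  structure(list(values = values, modality = modality,
                 cell_ids = as.character(cell_ids)),
            class = "latent_representation")
}

#' @export
print.latent_representation <- function(x, ...) {
  cat(sprintf("<latent_representation> %s: %d cells x %d\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# ---- integration training ---------------------------------------------------

check_task_dims <- function(Xmats, cfg) {
  widths <- vapply(Xmats, ncol, 1L)
  if (length(unique(widths)) != 1) {
    stop("all modalities must share the aligned width, got: ",
         paste(widths, collapse = ", "))
  }
  if (widths[1] %% cfg$s != 0) {
    stop(sprintf("aligned width %d is not divisible by s=%d",
                 widths[1], cfg$s))
  }
  invisible(widths[1])
}

#' Train the integration model on a paired multimodal dataset
#'
#' Mini-batch Adam training of the multi-task objective
#' `lambda * sum_m Loss_rec(m) + Loss_comb`, drawing the same cell indices
#' across all modalities in every batch.  All randomness (initialisation,
#' batch order, dropout) is governed by `cfg$seed`, so runs are bitwise
#' reproducible.
#'
#' @param ds A reduced-layer [pair()]ed dataset (see [preprocess_paired()]).
#' @param cfg An [scm_config()].
#' @param verbose Print one line per epoch.
#' @return An `scm_model` with an attached `trace` data frame (epoch, total
#'   loss, reconstruction and fusion components).
#' @export
train_integration <- function(ds, cfg = scm_config(), verbose = FALSE) {
  stopifnot(inherits(ds, "paired_dataset"))
  if (length(ds$modalities) < 2) stop("integration needs >= 2 modalities")
  Xmats <- lapply(ds$modalities, `[[`, "values")
  D <- check_task_dims(Xmats, cfg)
  n <- nrow(Xmats[[1]])
  set.seed(cfg$seed)
  plan <- make_seq_plan(vapply(Xmats, ncol, 1L), cfg$s)
  model <- init_model(cfg, plan$P, length(Xmats),
                      head_dims = vapply(Xmats, ncol, 1L))
  st <- adam_init(model$weights)
  n_mod <- length(Xmats)
  pairs <- utils::combn(n_mod, 2)
  npairs <- ncol(pairs)
  mn <- names(Xmats)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      rec = numeric(0), comb = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep_loss <- ep_rec <- ep_comb <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      nb <- length(idx)
      Xb <- lapply(Xmats, function(x) x[idx, , drop = FALSE])
      fw <- model_forward(model, Xb, training = TRUE, keep_cache = TRUE)
      rec_losses <- vapply(mn, function(m) {
        loss_rec(fw$recon[[m]], Xb[[m]])
      }, 1)
      comb <- loss_comb(fw$latents)
      total <- loss_integration(rec_losses, comb, cfg$lambda_rec)
      if (!is.finite(total)) {
        stop(sprintf("non-finite loss in epoch %d, batch %d", ep, bi))
      }
      dRecon <- lapply(mn, function(m) {
        cfg$lambda_rec * 2 * (fw$recon[[m]] - Xb[[m]]) / length(Xb[[m]])
      })
      names(dRecon) <- mn
      dLat <- lapply(fw$latents, function(L) L * 0)
      for (p in seq_len(npairs)) {
        a <- mn[pairs[1, p]]; b <- mn[pairs[2, p]]
        diff <- fw$latents[[a]] - fw$latents[[b]]
        g <- 2 * diff / (length(diff) * npairs)
        dLat[[a]] <- dLat[[a]] + g
        dLat[[b]] <- dLat[[b]] - g
      }
      grads <- model_backward(model, fw, dLatents = dLat, dRecon = dRecon)
      upd <- adam_step(model$weights, grads, st, cfg$lr)
      model$weights <- upd$weights
      st <- upd$state
      ep_loss <- ep_loss + total * nb
      ep_rec <- ep_rec + sum(rec_losses) * nb
      ep_comb <- ep_comb + comb * nb
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / n,
                                     rec = ep_rec / n, comb = ep_comb / n))
    if (verbose) {
      message(sprintf("epoch=%d loss=%.6g rec=%.6g comb=%.6g",
                      ep, ep_loss / n, ep_rec / n, ep_comb / n))
    }
  }
  model$trace <- trace
  model$meta$task <- "integration"
  model$meta$modalities <- mn
  model
}

#' Extract per-modality latent representations
#'
#' Deterministic forward pass (dropout off) through a trained integration
#' model; decoder outputs are average-pooled over each modality's
#' sub-vector positions.
#'
#' @param model A trained `scm_model` (integration task).
#' @param ds The reduced paired dataset (any cell subset, same widths as
#'   training).
#' @param batch_size Cells per forward chunk (memory control only; does not
#'   change results).
#' @return Named list of `latent_representation` objects (`cells x s`).
#' @export
extract_latents <- function(model, ds, batch_size = 512) {
  stopifnot(inherits(ds, "paired_dataset"))
  Xmats <- lapply(ds$modalities, `[[`, "values")
  check_task_dims(Xmats, model$config)
  n <- nrow(Xmats[[1]])
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  parts <- lapply(chunks, function(idx) {
    fw <- model_forward(model,
                        lapply(Xmats, function(x) x[idx, , drop = FALSE]),
                        training = FALSE)
    fw$latents
  })
  out <- list()
  for (m in names(parts[[1]])) {
    vals <- do.call(rbind, lapply(parts, `[[`, m))
    rownames(vals) <- ds$modalities[[m]]$cell_ids
    out[[m]] <- latent_representation(vals, ds$modalities[[m]]$modality,
                                      ds$modalities[[m]]$cell_ids)
  }
  out
}

# ---- generation training ----------------------------------------------------

#' Train a cross-modality generation model
#'
#' The source modality's reduced sub-vectors pass through the causally
#' masked decoder; the pooled latent feeds a linear head onto the measured
#' target modality (normalized scale), trained with plain MSE.
#'
#' @param source A reduced-layer [modality_matrix()] (the measured
#'   modality).
#' @param target A normalized-layer [modality_matrix()] (the modality to be
#'   generated), row-paired with `source`.
#' @param cfg An [scm_config()].  Generation defaults to 300 epochs: its
#'   objective has a single MSE term, so each update carries less signal
#'   than the multi-task integration loss, and at desk scale 300 epochs
#'   still train in about a minute.
#' @param verbose Print one line per epoch.
#' @return An `scm_model` with `trace`; use [generate()] for prediction.
#' @export
train_generation <- function(source, target,
                             cfg = scm_config(epochs = 300),
                             verbose = FALSE) {
  stopifnot(inherits(source, "modality_matrix"),
            inherits(target, "modality_matrix"))
  if (nrow(source$values) != nrow(target$values)) {
    stop("source and target must be row-paired")
  }
  X <- source$values
  Y <- target$values
  if (ncol(X) %% cfg$s != 0) {
    stop(sprintf("source width %d is not divisible by s=%d",
                 ncol(X), cfg$s))
  }
  n <- nrow(X)
  set.seed(cfg$seed)
  src <- source$modality
  tgt <- target$modality
  if (identical(src, tgt)) tgt <- paste0(tgt, "_target")
  plan <- make_seq_plan(stats::setNames(ncol(X), src), cfg$s)
  hd <- stats::setNames(ncol(Y), tgt)
  model <- init_model(cfg, plan$P, 1L, head_dims = hd)
  st <- adam_init(model$weights)
  trace <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      Xb <- list(X[idx, , drop = FALSE])
      names(Xb) <- src
      fw <- model_forward(model, Xb, training = TRUE, keep_cache = TRUE)
      pred <- fw$recon[[tgt]]
      Yb <- Y[idx, , drop = FALSE]
      total <- loss_rec(pred, Yb)
      if (!is.finite(total)) {
        stop(sprintf("non-finite loss in epoch %d, batch %d", ep, bi))
      }
      dRecon <- stats::setNames(list(2 * (pred - Yb) / length(Yb)), tgt)
      grads <- model_backward(model, fw, dRecon = dRecon)
      upd <- adam_step(model$weights, grads, st, cfg$lr)
      model$weights <- upd$weights
      st <- upd$state
      ep_loss <- ep_loss + total * length(idx)
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / n))
    if (verbose) message(sprintf("epoch=%d loss=%.6g", ep, ep_loss / n))
  }
  model$trace <- trace
  model$meta$task <- "generation"
  model$meta$source_modality <- src
  model$meta$target_modality <- tgt
  model$meta$source_dim <- ncol(X)
  model$meta$target_features <- target$feature_ids
  model
}

#' Generate the unmeasured modality from a measured one
#'
#' Deterministic single forward pass: source sub-vectors through the
#' decoder, pooled latent through the target reconstruction head.
#'
#' @param model A trained generation `scm_model`.
#' @param source A reduced-layer [modality_matrix()] (or bare matrix)
#'   preprocessed identically to training.
#' @return Numeric matrix `cells x v_target` with the training target's
#'   feature names.
#' @export
generate <- function(model, source) {
  if (!identical(model$meta$task, "generation")) {
    stop("generate() needs a model trained with train_generation()")
  }
  X <- if (inherits(source, "modality_matrix")) source$values
       else as.matrix(source)
  if (ncol(X) != model$meta$source_dim) {
    stop(sprintf("source width %d does not match training width %d",
                 ncol(X), model$meta$source_dim))
  }
  Xl <- stats::setNames(list(X), model$meta$source_modality)
  fw <- model_forward(model, Xl, training = FALSE)
  pred <- fw$recon[[model$meta$target_modality]]
  rownames(pred) <- rownames(X)
  colnames(pred) <- unlist(model$meta$target_features)
  pred
}
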