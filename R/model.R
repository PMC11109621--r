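# The scTransformer decoder.
#
# Forward map per layer (pre-norm residuals):
#   X1 = X + Dropout(Merge(MultiHead(LayerNorm1(X))))
#   X2 = X1 + Dropout(ReLU(LayerNorm2(X1) W1 + b1)) W2 + b2
# with scm-attention per head:
#   Q,K,V = ReLU(split(Xn W_qkv + b)),  S = Q K^T / sqrt(s)  (causal mask),
#   head  = ReLU(S) V      -- ReLU replaces softmax throughout.
#
# The batch lives in a 2D "row block" layout: row (i-1)*P + p is token p of
# cell i, so every projection is one matrix multiply; only the P x P score
# matrices are formed per cell and head.  The backward pass is derived
# analytically (see the methods vignette) and verified in the test suite
# against central finite differences.

LN_EPS <- 1e-5

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# He (Kaiming) initialisation for projections feeding a ReLU
he <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

init_layer_weights <- function(s) {
  list(
    W_qkv = he(s, 3 * s),
    b_qkv = numeric(3 * s),
    W_out = xavier(s, s),
    g1 = rep(1, s), be1 = numeric(s),
    g2 = rep(1, s), be2 = numeric(s),
    W1 = he(s, 2 * s), b1 = numeric(2 * s),
    W2 = xavier(2 * s, s), b2 = numeric(s)
  )
}

#' Initialise model weights
#'
#' @param cfg An [scm_config()].
#' @param n_positions Total number of sub-vector positions in the (joint)
#'   input sequence.
#' @param n_modality_codes Number of distinct modality codes.
#' @param head_dims Named integer vector: output width of each linear
#'   reconstruction head (one per modality being reconstructed/generated).
#' @return An `scm_model` object (fields `weights`, `config`, `meta`);
#'   weights are drawn from the current RNG state.
#' @export
init_model <- function(cfg, n_positions, n_modality_codes, head_dims) {
  s <- cfg$s
  weights <- list(
    pos = matrix(stats::rnorm(n_positions * s, sd = 0.02), n_positions, s),
    mod = matrix(stats::rnorm(n_modality_codes * s, sd = 0.02),
                 n_modality_codes, s),
    layers = lapply(seq_len(cfg$n_layers), function(l) init_layer_weights(s)),
    heads = lapply(head_dims, function(v) {
      list(W = xavier(s, v), b = numeric(v))
    })
  )
  if (cfg$identity_merge) {
    for (l in seq_along(weights$layers)) {
      weights$layers[[l]]$W_out <- diag(s)
    }
  }
  structure(list(weights = weights, config = cfg,
                 meta = list(n_positions = n_positions,
                             n_modality_codes = n_modality_codes,
                             head_dims = as.list(head_dims))),
            class = "scm_model")
}

#' @export
print.scm_model <- function(x, ...) {
  cat(sprintf(
    "<scm_model> s=%d H=%d layers=%d positions=%d heads: %s\n",
    x$config$s, x$config$H, x$config$n_layers, x$meta$n_positions,
    paste(names(x$meta$head_dims), unlist(x$meta$head_dims),
          sep = ":", collapse = ", ")))
  invisible(x)
}

# ---- layer normalization ----------------------------------------------------

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(va + LN_EPS)
  xhat <- xc * invstd
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, invstd = invstd)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- attention --------------------------------------------------------------

# X row-block (n*P x s); returns output row-block plus cache for backward
attention_forward <- function(Xn, lw, cfg, n, P, mask = NULL) {
  s <- cfg$s; H <- cfg$H; sh <- s %/% H
  if (is.null(mask)) mask <- lower.tri(matrix(TRUE, P, P), diag = TRUE)
  Z <- Xn %*% lw$W_qkv + rep(lw$b_qkv, each = nrow(Xn))
  QKV <- pmax(Z, 0)
  O <- matrix(0, n * P, s)
  att <- vector("list", n)
  inv_sqrt_s <- 1 / sqrt(s)
  for (i in seq_len(n)) {
    ri <- ((i - 1) * P + 1):(i * P)
    ai <- vector("list", H)
    for (h in seq_len(H)) {
      hc <- ((h - 1) * sh + 1):(h * sh)
      Q <- QKV[ri, hc, drop = FALSE]
      K <- QKV[ri, s + hc, drop = FALSE]
      V <- QKV[ri, 2 * s + hc, drop = FALSE]
      S <- tcrossprod(Q, K) * inv_sqrt_s
      S[!mask] <- -Inf
      A <- pmax(S, 0)
      O[ri, hc] <- A %*% V
      ai[[h]] <- A
    }
    att[[i]] <- ai
  }
  merged <- if (cfg$identity_merge) O else O %*% lw$W_out
  list(out = merged, Z = Z, QKV = QKV, att = att, O = O, mask = mask)
}

attention_backward <- function(dmerged, cache, Xn, lw, cfg, n, P) {
  s <- cfg$s; H <- cfg$H; sh <- s %/% H
  QKV <- cache$QKV
  if (cfg$identity_merge) {
    dO <- dmerged
    dW_out <- matrix(0, s, s)
  } else {
    dO <- dmerged %*% t(lw$W_out)
    dW_out <- crossprod(cache$O, dmerged)
  }
  dQKV <- matrix(0, n * P, 3 * s)
  inv_sqrt_s <- 1 / sqrt(s)
  for (i in seq_len(n)) {
    ri <- ((i - 1) * P + 1):(i * P)
    for (h in seq_len(H)) {
      hc <- ((h - 1) * sh + 1):(h * sh)
      A <- cache$att[[i]][[h]]
      Q <- QKV[ri, hc, drop = FALSE]
      K <- QKV[ri, s + hc, drop = FALSE]
      V <- QKV[ri, 2 * s + hc, drop = FALSE]
      dOh <- dO[ri, hc, drop = FALSE]
      dA <- tcrossprod(dOh, V)
      dS <- dA * (A > 0)            # ReLU' on scores; masked entries are 0
      dQKV[ri, hc] <- dQKV[ri, hc] + dS %*% K * inv_sqrt_s
      dQKV[ri, s + hc] <- dQKV[ri, s + hc] + crossprod(dS, Q) * inv_sqrt_s
      dQKV[ri, 2 * s + hc] <- dQKV[ri, 2 * s + hc] + crossprod(A, dOh)
    }
  }
  dZ <- dQKV * (cache$Z > 0)
  list(dXn = dZ %*% t(lw$W_qkv),
       dW_qkv = crossprod(Xn, dZ),
       db_qkv = colSums(dZ),
       dW_out = dW_out)
}

# ---- decoder layer ----------------------------------------------------------

dropout_mask <- function(nr, nc, drop_rate) {
  keep <- 1 - drop_rate
  matrix((stats::runif(nr * nc) < keep) / keep, nr, nc)
}

layer_forward <- function(X, lw, cfg, n, P, training = FALSE, mask = NULL) {
  ln1 <- ln_forward(X, lw$g1, lw$be1)
  att <- attention_forward(ln1$y, lw, cfg, n, P, mask)
  attn_out <- att$out
  dm_att <- NULL
  if (training && cfg$drop_rate > 0) {
    dm_att <- dropout_mask(nrow(X), ncol(X), cfg$drop_rate)
    attn_out <- attn_out * dm_att
  }
  X1 <- X + attn_out
  ln2 <- ln_forward(X1, lw$g2, lw$be2)
  Hpre <- ln2$y %*% lw$W1 + rep(lw$b1, each = nrow(X))
  Hr <- pmax(Hpre, 0)
  dm_ff <- NULL
  if (training && cfg$drop_rate > 0) {
    dm_ff <- dropout_mask(nrow(Hr), ncol(Hr), cfg$drop_rate)
    Hr <- Hr * dm_ff
  }
  FF <- Hr %*% lw$W2 + rep(lw$b2, each = nrow(X))
  X2 <- X1 + FF
  list(out = X2,
       cache = list(X = X, ln1 = ln1, att = att, dm_att = dm_att, X1 = X1,
                    ln2 = ln2, Hpre = Hpre, Hr = Hr, dm_ff = dm_ff))
}

layer_backward <- function(dX2, cache, lw, cfg, n, P) {
  # feed-forward branch
  dFF <- dX2
  dHr <- dFF %*% t(lw$W2)
  dW2 <- crossprod(cache$Hr, dFF)
  db2 <- colSums(dFF)
  if (!is.null(cache$dm_ff)) dHr <- dHr * cache$dm_ff
  dHpre <- dHr * (cache$Hpre > 0)
  dW1 <- crossprod(cache$ln2$y, dHpre)
  db1 <- colSums(dHpre)
  dln2y <- dHpre %*% t(lw$W1)
  ln2b <- ln_backward(dln2y, cache$ln2, lw$g2)
  dX1 <- dX2 + ln2b$dx
  # attention branch
  dattn <- dX1
  if (!is.null(cache$dm_att)) dattn <- dattn * cache$dm_att
  attb <- attention_backward(dattn, cache$att, cache$ln1$y, lw, cfg, n, P)
  ln1b <- ln_backward(attb$dXn, cache$ln1, lw$g1)
  dX <- dX1 + ln1b$dx
  list(dX = dX,
       grads = list(W_qkv = attb$dW_qkv, b_qkv = attb$db_qkv,
                    W_out = attb$dW_out,
                    g1 = ln1b$dgamma, be1 = ln1b$dbeta,
                    g2 = ln2b$dgamma, be2 = ln2b$dbeta,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- full network on a joint multimodal sequence ---------------------------

# seq_plan: list(P_total, offsets (named, 0-based), P_m (named),
#                codes (length P_total, 0-based), slices (named 1-based
#                position indices))
make_seq_plan <- function(dims_by_modality, s) {
  P_m <- vapply(dims_by_modality, function(D) {
    if (D %% s != 0) {
      stop(sprintf("modality width %d not divisible by s=%d", D, s))
    }
    D %/% s
  }, 1L)
  offsets <- cumsum(c(0L, utils::head(P_m, -1)))
  names(offsets) <- names(P_m)
  P <- sum(P_m)
  codes <- integer(P)
  slices <- list()
  for (k in seq_along(P_m)) {
    idx <- offsets[k] + seq_len(P_m[k])
    codes[idx] <- k - 1L
    slices[[names(P_m)[k]]] <- idx
  }
  list(P = P, P_m = P_m, offsets = offsets, codes = codes, slices = slices)
}

# Xmats: named list of n x D_m matrices (reduced layer), same cell order
build_sequence <- function(Xmats, plan, s) {
  n <- nrow(Xmats[[1]])
  X <- matrix(0, n * plan$P, s)
  for (m in names(Xmats)) {
    rows_m <- rep((seq_len(n) - 1L) * plan$P, each = plan$P_m[[m]]) +
      plan$offsets[[m]] + seq_len(plan$P_m[[m]])
    X[rows_m, ] <- patch_rows(Xmats[[m]], s)
  }
  X
}

model_forward <- function(model, Xmats, training = FALSE,
                          keep_cache = FALSE) {
  cfg <- model$config
  w <- model$weights
  s <- cfg$s
  n <- nrow(Xmats[[1]])
  plan <- make_seq_plan(vapply(Xmats, ncol, 1L), s)
  if (plan$P != nrow(w$pos)) {
    stop(sprintf("model was built for %d positions, input has %d",
                 nrow(w$pos), plan$P))
  }
  Xtok <- build_sequence(Xmats, plan, s)
  emb <- w$pos[rep(seq_len(plan$P), n), , drop = FALSE] +
    w$mod[rep(plan$codes + 1L, n), , drop = FALSE]
  X <- Xtok + emb
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lf <- layer_forward(X, w$layers[[l]], cfg, n, plan$P, training)
    X <- lf$out
    caches[[l]] <- if (keep_cache) lf$cache else NULL
  }
  latents <- list()
  for (m in names(plan$slices)) {
    rows_m <- rep((seq_len(n) - 1L) * plan$P, each = plan$P_m[[m]]) +
      plan$offsets[[m]] + seq_len(plan$P_m[[m]])
    grp <- rep(seq_len(n), each = plan$P_m[[m]])
    latents[[m]] <- rowsum(X[rows_m, , drop = FALSE], grp,
                           reorder = FALSE) / plan$P_m[[m]]
  }
  recon <- list()
  for (m in names(w$heads)) {
    if (!is.null(latents[[m]])) {
      recon[[m]] <- latents[[m]] %*% w$heads[[m]]$W +
        rep(w$heads[[m]]$b, each = n)
    } else if (length(latents) == 1) {
      # generation: single source modality feeds every (target) head
      recon[[m]] <- latents[[1]] %*% w$heads[[m]]$W +
        rep(w$heads[[m]]$b, each = n)
    }
  }
  list(latents = latents, recon = recon, plan = plan, n = n,
       caches = if (keep_cache) caches else NULL, Xfinal = X)
}

# dLatents / dRecon: named lists (may be NULL entries); latent gradients
# from the heads are added internally.
model_backward <- function(model, fw, dLatents = list(), dRecon = list()) {
  cfg <- model$config
  w <- model$weights
  n <- fw$n
  plan <- fw$plan
  grads <- list(pos = matrix(0, nrow(w$pos), cfg$s),
                mod = matrix(0, nrow(w$mod), cfg$s),
                layers = vector("list", cfg$n_layers),
                heads = list())
  dLat <- lapply(fw$latents, function(L) matrix(0, n, cfg$s))
  for (m in names(fw$latents)) {
    if (!is.null(dLatents[[m]])) dLat[[m]] <- dLat[[m]] + dLatents[[m]]
  }
  for (m in names(dRecon)) {
    if (is.null(dRecon[[m]])) next
    hm <- w$heads[[m]]
    src <- if (!is.null(fw$latents[[m]])) m else names(fw$latents)[1]
    grads$heads[[m]] <- list(W = crossprod(fw$latents[[src]], dRecon[[m]]),
                             b = colSums(dRecon[[m]]))
    dLat[[src]] <- dLat[[src]] + dRecon[[m]] %*% t(hm$W)
  }
  for (m in names(w$heads)) {
    if (is.null(grads$heads[[m]])) {
      grads$heads[[m]] <- list(W = matrix(0, cfg$s, ncol(w$heads[[m]]$W)),
                               b = numeric(ncol(w$heads[[m]]$W)))
    }
  }
  dX <- matrix(0, n * plan$P, cfg$s)
  for (m in names(fw$latents)) {
    rows_m <- rep((seq_len(n) - 1L) * plan$P, each = plan$P_m[[m]]) +
      plan$offsets[[m]] + seq_len(plan$P_m[[m]])
    grp <- rep(seq_len(n), each = plan$P_m[[m]])
    dX[rows_m, ] <- dX[rows_m, ] + dLat[[m]][grp, , drop = FALSE] /
      plan$P_m[[m]]
  }
  for (l in rev(seq_len(cfg$n_layers))) {
    lb <- layer_backward(dX, fw$caches[[l]], w$layers[[l]], cfg, n, plan$P)
    dX <- lb$dX
    grads$layers[[l]] <- lb$grads
  }
  # embedding tables: sum dX over cells per position / per code
  pos_idx <- rep(seq_len(plan$P), n)
  grads$pos <- rowsum(dX, pos_idx, reorder = TRUE)
  code_idx <- rep(plan$codes + 1L, n)
  gm <- rowsum(dX, code_idx, reorder = TRUE)
  grads$mod[as.integer(rownames(gm)), ] <- gm
  if (cfg$identity_merge) {
    for (l in seq_len(cfg$n_layers)) {
      grads$layers[[l]]$W_out[] <- 0
    }
  }
  grads
}

# ---- public single-piece operations (spec surface) -------------------------

#' scm-attention on a batch of sub-vector sequences
#'
#' ReLU-activated query/key/value projections, scaled dot-product scores
#' with a causal (or caller-supplied) mask, ReLU in place of softmax, heads
#' computed in parallel and concatenated, then optionally merged.
#'
#' @param X Numeric array `n_cells x n_sub x s`.
#' @param weights List with `W_qkv` (`s x 3s`), `b_qkv` (`3s`), optional
#'   `W_out` (`s x s`; `NULL` skips the merge).
#' @param H Number of heads (`s %% H == 0`).
#' @param mask Logical `n_sub x n_sub`, `TRUE` where key position j may be
#'   attended from query position i; defaults to causal `j <= i`.
#' @return Numeric array `n_cells x n_sub x s`.
#' @export
scm_attention <- function(X, weights, H = 1L, mask = NULL) {
  d <- dim(X)
  stopifnot(length(d) == 3)
  s <- d[3]
  if (!all(is.finite(weights$W_qkv))) stop("non-finite attention weights")
  cfg <- list(s = s, H = as.integer(H),
              identity_merge = is.null(weights$W_out))
  lw <- list(W_qkv = weights$W_qkv,
             b_qkv = if (is.null(weights$b_qkv)) numeric(3 * s)
                     else weights$b_qkv,
             W_out = weights$W_out)
  out <- attention_forward(as_row_blocks(X), lw, cfg, d[1], d[2], mask)
  as_array3(out$out, d[1], d[2])
}

#' One scTransformer decoder layer
#'
#' Pre-norm residual block: multi-head scm-attention over the layer-normed
#' input plus a two-layer ReLU feed-forward network of inner width `2s`.
#'
#' @param X Numeric array `n_cells x n_sub x s`.
#' @param weights A layer weight list (`W_qkv`, `b_qkv`, `W_out`, LayerNorm
#'   `g1`/`be1`/`g2`/`be2`, `W1`/`b1`/`W2`/`b2`), as produced by
#'   [init_model()] (element of `weights$layers`).
#' @param H Number of attention heads.
#' @param mask Optional attention mask (default causal).
#' @return Numeric array of the same shape.
#' @export
decoder_layer <- function(X, weights, H = 1L, mask = NULL) {
  d <- dim(X)
  stopifnot(length(d) == 3)
  cfg <- list(s = d[3], H = as.integer(H), drop_rate = 0,
              identity_merge = FALSE)
  out <- layer_forward(as_row_blocks(X), weights, cfg, d[1], d[2],
                       training = FALSE, mask = mask)
  as_array3(out$out, d[1], d[2])
}

#' Average-pool decoder outputs into per-modality latents
#'
#' @param X Numeric array `n_cells x n_sub x s` of decoder outputs.
#' @param slices Named list of 1-based position index vectors, one per
#'   modality; together they must partition `1..n_sub`.
#' @return Named list of `n_cells x s` latent matrices.
#' @export
pool_latent <- function(X, slices) {
  d <- dim(X)
  stopifnot(length(d) == 3)
  idx <- sort(unlist(slices, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(d[2]))) {
    stop("slices must partition positions 1..n_sub without overlap")
  }
  lapply(slices, function(sl) {
    if (length(sl) == 0) stop("empty modality slice")
    if (length(sl) == 1) {
      matrix(X[, sl, ], d[1], d[3])
    } else {
      apply(X[, sl, , drop = FALSE], c(1, 3), mean)
    }
  })
}

#' Linear reconstruction head
#'
#' `X_reconstruction = X_average W + b`: a single affine map from the
#' pooled latent to the target feature space, no activation.
#'
#' @param latent Numeric matrix `n_cells x s`.
#' @param head List with `W` (`s x v_out`) and `b` (`v_out`).
#' @return Numeric matrix `n_cells x v_out`.
#' @export
reconstruct <- function(latent, head) {
  latent <- as.matrix(latent)
  if (ncol(latent) != nrow(head$W)) {
    stop(sprintf("latent width %d does not match head input width %d",
                 ncol(latent), nrow(head$W)))
  }
  latent %*% head$W + rep(head$b, each = nrow(latent))
}
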