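# Cells Embedding: partition each cell's aligned expression vector into
# length-s sub-vectors (attention tokens) and add positional and modality
# codes.  Position and modality are injected as learned additive embeddings
# of width s rather than appended scalars, which keeps the decoder's
# s x 3s projection shapes intact; see the methods vignette.

#' Partition cells into sub-vectors
#'
#' Splits each row of an `n x D` matrix into `n_sub = ceiling(D / s)`
#' contiguous sub-vectors of length `s`; the final sub-vector is
#' zero-padded when `s` does not divide `D`.  [unpatch()] inverts the
#' operation exactly.
#'
#' @param cells Numeric matrix, cells x aligned features.
#' @param s Sub-vector length (`1 <= s <= D`).
#' @param modality_code Integer code (0-based) identifying the modality of
#'   every sub-vector in this batch.
#' @return An object of class `sub_vector_batch`: list with `values`
#'   (array `n x n_sub x s`), `positions` (0-based), `modality_codes`,
#'   `pad_width`, `source_dim`.
#' @export
patch <- function(cells, s, modality_code = 0L) {
  cells <- as.matrix(cells)
  D <- ncol(cells)
  n <- nrow(cells)
  if (s < 1) stop("s must be >= 1")
  if (s > D) stop(sprintf("degenerate patching: s (%d) > D (%d)", s, D))
  n_sub <- ceiling(D / s)
  pad <- n_sub * s - D
  padded <- if (pad > 0) cbind(cells, matrix(0, n, pad)) else cells
  # row-major split: token p of cell i is columns (p-1)*s + 1 ... p*s
  values <- array(0, dim = c(n, n_sub, s))
  for (p in seq_len(n_sub)) {
    values[, p, ] <- padded[, ((p - 1) * s + 1):(p * s), drop = FALSE]
  }
  structure(list(values = values,
                 positions = 0:(n_sub - 1),
                 modality_codes = rep.int(as.integer(modality_code), n_sub),
                 pad_width = as.integer(pad),
                 source_dim = as.integer(D)),
            class = "sub_vector_batch")
}

#' @rdname patch
#' @param batch A `sub_vector_batch`.
#' @export
unpatch <- function(batch) {
  stopifnot(inherits(batch, "sub_vector_batch"))
  v <- batch$values
  n <- dim(v)[1]; n_sub <- dim(v)[2]; s <- dim(v)[3]
  out <- matrix(0, n, n_sub * s)
  for (p in seq_len(n_sub)) {
    out[, ((p - 1) * s + 1):(p * s)] <- v[, p, ]
  }
  out[, seq_len(batch$source_dim), drop = FALSE]
}

#' Add positional and modality encodings
#'
#' `output[i, p, ] = values[i, p, ] + pos_table[p, ] + mod_table[code(p), ]`
#' with learned width-`s` embedding tables.
#'
#' @param batch A `sub_vector_batch`.
#' @param pos_table Numeric matrix `n_positions x s`, row `p + 1` used for
#'   0-based position `p`.
#' @param mod_table Numeric matrix `n_modalities x s`, row `code + 1` used
#'   for 0-based modality code `code`.
#' @return Numeric array `n x n_sub x s`.
#' @export
encode <- function(batch, pos_table, mod_table) {
  stopifnot(inherits(batch, "sub_vector_batch"))
  v <- batch$values
  n_sub <- dim(v)[2]; s <- dim(v)[3]
  if (max(batch$positions) + 1 > nrow(pos_table)) {
    stop("position out of range of pos_table")
  }
  if (max(batch$modality_codes) + 1 > nrow(mod_table)) {
    stop("modality code out of range of mod_table")
  }
  if (ncol(pos_table) != s || ncol(mod_table) != s) {
    stop("embedding table width != s")
  }
  n <- dim(v)[1]
  out <- v
  for (p in seq_len(n_sub)) {
    add <- pos_table[batch$positions[p] + 1, ] +
      mod_table[batch$modality_codes[p] + 1, ]
    out[, p, ] <- v[, p, ] + rep(add, each = n)
  }
  out
}

# ---- internal row-block layout ---------------------------------------------
# The model works on a 2D layout: row (i-1)*P + p holds token p of cell i.
# This keeps all projections as single matrix multiplies.

as_row_blocks <- function(arr3) {
  d <- dim(arr3)
  m <- matrix(0, d[1] * d[2], d[3])
  # rows of cell i are contiguous: row (i-1)*P + p holds token p of cell i
  for (i in seq_len(d[1])) {
    m[((i - 1) * d[2] + 1):(i * d[2]), ] <- arr3[i, , ]
  }
  m
}

as_array3 <- function(m, n, P) {
  s <- ncol(m)
  arr <- array(0, dim = c(n, P, s))
  for (i in seq_len(n)) {
    arr[i, , ] <- m[((i - 1) * P + 1):(i * P), , drop = FALSE]
  }
  arr
}

# patch a cells x D matrix directly into the row-block layout (fast path,
# no padding support needed because aligned_dim %% s == 0 is enforced)
patch_rows <- function(cells, s) {
  D <- ncol(cells)
  stopifnot(D %% s == 0)
  P <- D %/% s
  n <- nrow(cells)
  # token p of cell i = cells[i, (p-1)*s + (1:s)]; build by column reshuffle
  m <- matrix(0, n * P, s)
  for (p in seq_len(P)) {
    m[seq.int(p, n * P, by = P), ] <- cells[, ((p - 1) * s + 1):(p * s),
                                            drop = FALSE]
  }
  m
}
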