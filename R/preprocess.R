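# Normalization, feature selection and dimension alignment.  All modalities
# leave this module as equal-width `reduced` matrices ready for patching.

#' Library-size normalize and log-transform a count matrix
#'
#' Each cell is scaled to a common total (`target_sum`) and then
#' `log(1 + x)` transformed — the standard recipe for RNA counts, also used
#' for ATAC when TF-IDF is disabled.  Cells with zero total counts are left
#' as all-zero rows with a warning.
#'
#' @param m A raw-layer [modality_matrix()] (`rna`, or `atac`).
#' @param cfg A [preprocess_config()].
#' @return A normalized-layer [modality_matrix()].
#' @export
normalize_rna <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "modality_matrix"))
  if (m$layer != "raw") stop("normalize_rna expects a raw-layer matrix")
  if (m$modality == "protein") stop("use normalize_protein for protein data")
  x <- m$values
  totals <- rowSums(x)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts left as zero rows")
    totals[zero] <- 1
  }
  y <- log1p(x / totals * cfg$target_sum)
  modality_matrix(y, m$cell_ids, m$feature_ids, modality = m$modality,
                  layer = "normalized")
}

#' Centered log-ratio normalization for protein counts
#'
#' Per cell, `y_j = log((x_j + c) / g)` with `g` the geometric mean of
#' `x_j + c` across the panel and `c` a pseudocount; every output row sums
#' to zero.  This is the count-compatible CLR variant standard for
#' antibody-derived tag panels.
#'
#' @inheritParams normalize_rna
#' @return A normalized-layer [modality_matrix()].
#' @export
normalize_protein <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "modality_matrix"))
  if (m$layer != "raw") stop("normalize_protein expects a raw-layer matrix")
  if (any(m$values < 0)) stop("protein counts must be non-negative")
  lx <- log(m$values + cfg$clr_pseudocount)
  y <- lx - rowMeans(lx)
  modality_matrix(y, m$cell_ids, m$feature_ids, modality = m$modality,
                  layer = "normalized")
}

#' TF-IDF weighting for peak count matrices
#'
#' Term-frequency (per-cell fraction) times inverse document frequency
#' `log(1 + n_cells / (1 + n_cells_with_peak))`, then `log1p` scaling.
#'
#' @inheritParams normalize_rna
#' @return A normalized-layer [modality_matrix()].
#' @export
normalize_atac_tfidf <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "modality_matrix"))
  if (m$layer != "raw") stop("normalize_atac_tfidf expects raw counts")
  x <- m$values
  totals <- rowSums(x)
  totals[totals == 0] <- 1
  tf <- x / totals
  idf <- log1p(nrow(x) / (1 + colSums(x > 0)))
  y <- log1p(sweep(tf, 2, idf, `*`) * cfg$target_sum)
  modality_matrix(y, m$cell_ids, m$feature_ids, modality = m$modality,
                  layer = "normalized")
}

#' Highly variable feature selection by binned dispersion
#'
#' Features are ranked by their dispersion (variance / mean) z-scored
#' within equal-frequency mean bins, and the top `n_hvg` are kept in their
#' original column order.  If the matrix already has `<= n_hvg` features it
#' is returned unchanged.
#'
#' @param m A normalized-layer [modality_matrix()].
#' @param n_hvg Number of features to keep (>= 2).
#' @param n_bins Number of mean bins for dispersion standardisation.
#' @return A normalized-layer [modality_matrix()] with `n_hvg` columns.
#' @export
select_hvg <- function(m, n_hvg, n_bins = 20) {
  stopifnot(inherits(m, "modality_matrix"))
  if (m$layer != "normalized") stop("select_hvg expects a normalized matrix")
  if (n_hvg < 2) stop("n_hvg must be >= 2")
  if (ncol(m$values) <= n_hvg) return(m)
  score <- hvg_score(m$values, n_bins)
  keep <- sort(utils::head(order(score, decreasing = TRUE), n_hvg))
  modality_matrix(m$values[, keep, drop = FALSE], m$cell_ids,
                  m$feature_ids[keep], modality = m$modality,
                  layer = "normalized")
}

# dispersion = var/mean per feature, z-scored within equal-frequency mean
# bins; zero-mean features get score -Inf so they are never selected.
hvg_score <- function(x, n_bins = 20) {
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, max(1L, floor(ncol(x) / 2))))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(br) > 2) {
    cut(mu, breaks = br, include.lowest = TRUE)
  } else {
    factor(rep(1, length(mu)))
  }
  score <- numeric(length(mu))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    sdv <- stats::sd(disp[idx])
    if (is.na(sdv) || sdv == 0) {
      score[idx] <- 0
    } else {
      score[idx] <- (disp[idx] - mean(disp[idx])) / sdv
    }
  }
  score[mu == 0] <- -Inf
  score
}

#' Align all modalities to a common feature dimension
#'
#' Every modality is reduced to exactly `aligned_dim` columns by PCA on
#' column-centered data; a modality that already has `<= aligned_dim`
#' features (e.g. a small protein panel) is zero-padded instead.  With
#' `scale_total_var = TRUE` (default) each reduced matrix is finally
#' rescaled by one global factor to unit mean per-entry variance, so that
#' modalities enter the transformer on a common numeric scale while the
#' relative importance of the principal components is preserved.
#'
#' @param ds A [pair()]ed dataset whose modalities are normalized (and
#'   HVG-selected where applicable).
#' @param aligned_dim Target dimension `D` (must later be divisible by the
#'   sub-vector length `s`).
#' @param scale_total_var See above.
#' @return A `paired_dataset` whose modalities are reduced-layer matrices
#'   of identical width.
#' @export
align_dims <- function(ds, aligned_dim, scale_total_var = TRUE) {
  stopifnot(inherits(ds, "paired_dataset"))
  reduced <- lapply(ds$modalities, function(m) {
    r <- fit_reducer(m$values, aligned_dim, scale_total_var)
    y <- apply_reducer(r, m$values)
    fid <- if (r$kind == "pad") {
      c(m$feature_ids,
        if (r$pad > 0) paste0("pad_", seq_len(r$pad)) else character(0))
    } else {
      paste0("PC", seq_len(aligned_dim))
    }
    modality_matrix(y, m$cell_ids, fid, modality = m$modality,
                    layer = "reduced")
  })
  structure(list(modalities = reduced, pairing = ds$pairing,
                 labels = ds$labels),
            class = "paired_dataset")
}

# ---- fitted reducers (train-time fit, query-time apply) --------------------

fit_reducer <- function(x, aligned_dim, scale_total_var = TRUE, n = nrow(x)) {
  if (ncol(x) < aligned_dim) {
    r <- list(kind = "pad", in_features = colnames(x),
              pad = aligned_dim - ncol(x), center = NULL, rotation = NULL)
    active <- seq_len(ncol(x))
    y <- cbind(x, matrix(0, nrow(x), r$pad))
  } else {
    if (aligned_dim > n) {
      stop(sprintf(
        "aligned_dim (%d) exceeds cell count (%d): PCA rank insufficient",
        aligned_dim, n))
    }
    ctr <- colMeans(x)
    sv <- svd(sweep(x, 2, ctr), nu = 0, nv = aligned_dim)
    r <- list(kind = "pca", in_features = colnames(x), pad = 0L,
              center = ctr, rotation = sv$v)
    y <- sweep(x, 2, ctr) %*% sv$v
    active <- seq_len(aligned_dim)
  }
  r$scale <- 1
  if (scale_total_var) {
    vbar <- mean(apply(y[, active, drop = FALSE], 2, stats::var))
    if (is.finite(vbar) && vbar > 0) r$scale <- 1 / sqrt(vbar)
  }
  r
}

apply_reducer <- function(r, x) {
  if (!is.null(r$in_features) && !is.null(colnames(x))) {
    if (!all(r$in_features %in% colnames(x))) {
      stop("query is missing features the reducer was fitted on")
    }
    x <- x[, r$in_features, drop = FALSE]
  }
  y <- if (r$kind == "pad") {
    cbind(x, matrix(0, nrow(x), r$pad))
  } else {
    sweep(x, 2, r$center) %*% r$rotation
  }
  y * r$scale
}

#' Fit a modality preprocessor on training cells
#'
#' Records everything needed to preprocess new cells of the same modality
#' identically: the normalization recipe, the selected HVG set (RNA), and
#' the PCA basis / padding plan.  [apply_preprocessor()] replays it on a
#' raw query matrix.
#'
#' @param m A raw-layer [modality_matrix()] of training cells.
#' @param cfg A [preprocess_config()].
#' @return An object of class `scm_preprocessor`.
#' @export
fit_preprocessor <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "modality_matrix"))
  norm <- switch(m$modality,
    rna = select_hvg(normalize_rna(m, cfg), cfg$n_hvg),
    protein = normalize_protein(m, cfg),
    atac = if (cfg$atac_tfidf) normalize_atac_tfidf(m, cfg)
           else normalize_rna(m, cfg))
  reducer <- fit_reducer(norm$values, cfg$aligned_dim, cfg$scale_total_var)
  structure(list(modality = m$modality, cfg = cfg,
                 features = norm$feature_ids, reducer = reducer),
            class = "scm_preprocessor")
}

#' @rdname fit_preprocessor
#' @param pp An `scm_preprocessor`.
#' @param m_raw A raw-layer [modality_matrix()] of new cells with the same
#'   feature space as the training data.
#' @return A reduced-layer [modality_matrix()].
#' @export
apply_preprocessor <- function(pp, m_raw) {
  stopifnot(inherits(pp, "scm_preprocessor"),
            inherits(m_raw, "modality_matrix"))
  if (m_raw$modality != pp$modality) {
    stop("preprocessor was fitted on modality ", pp$modality)
  }
  cfg <- pp$cfg
  norm <- switch(m_raw$modality,
    rna = normalize_rna(m_raw, cfg),
    protein = normalize_protein(m_raw, cfg),
    atac = if (cfg$atac_tfidf) normalize_atac_tfidf(m_raw, cfg)
           else normalize_rna(m_raw, cfg))
  if (!all(pp$features %in% norm$feature_ids)) {
    stop("query feature space does not cover the training features")
  }
  x <- norm$values[, pp$features, drop = FALSE]
  y <- apply_reducer(pp$reducer, x)
  modality_matrix(y, m_raw$cell_ids,
                  if (pp$reducer$kind == "pad") {
                    c(pp$features, if (pp$reducer$pad > 0)
                        paste0("pad_", seq_len(pp$reducer$pad)))
                  } else {
                    paste0("PC", seq_len(ncol(y)))
                  },
                  modality = m_raw$modality, layer = "reduced")
}

#' Full preprocessing pipeline for a paired dataset
#'
#' Applies the modality-appropriate normalization (library-size + log for
#' RNA, CLR for protein, TF-IDF or the RNA recipe for ATAC), HVG selection
#' for RNA, then PCA dimension alignment.
#'
#' @param ds A raw-layer `paired_dataset`.
#' @param cfg A [preprocess_config()].
#' @return A list with `reduced` (the reduced `paired_dataset`) and
#'   `normalized` (the per-modality normalized matrices, used as generation
#'   targets).
#' @export
preprocess_paired <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "paired_dataset"))
  normalized <- lapply(ds$modalities, function(m) {
    switch(m$modality,
      rna = select_hvg(normalize_rna(m, cfg), cfg$n_hvg),
      protein = normalize_protein(m, cfg),
      atac = if (cfg$atac_tfidf) normalize_atac_tfidf(m, cfg)
             else normalize_rna(m, cfg))
  })
  nds <- structure(list(modalities = normalized, pairing = ds$pairing,
                        labels = ds$labels),
                   class = "paired_dataset")
  list(reduced = align_dims(nds, cfg$aligned_dim, cfg$scale_total_var),
       normalized = nds)
}
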