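# Evaluation suite: FOSCTTM alignment error, kNN label transfer with
# accuracy / macro-F1, and per-feature generation quality statistics.

as_embedding <- function(x) {
  if (inherits(x, "latent_representation")) x$values else as.matrix(x)
}

cross_dist <- function(X, Y) {
  # Euclidean distance matrix between rows of X and rows of Y
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

#' Fraction Of Samples Closer Than the True Match
#'
#' For row-paired embeddings `X`, `Y` (cell i of `X` matched with cell i of
#' `Y`): `n1(i)` counts cells `x_j` strictly closer to `y_i` than its true
#' match, `n2(i)` counts cells `y_j` strictly closer to `x_i` than its true
#' match, and `FOSCTTM = (1/2N) (sum n1(i)/N + sum n2(i)/N)`.  Euclidean
#' distance; ties are excluded, so identical embeddings score exactly 0.
#' 0 is perfect alignment, 0.5 the random baseline.
#'
#' @param X,Y Numeric matrices `N x d` (or `latent_representation`s) with
#'   row i of `X` paired with row i of `Y`.
#' @return Scalar in `[0, 1]`.
#' @export
foscttm <- function(X, Y) {
  X <- as_embedding(X); Y <- as_embedding(Y)
  if (!identical(dim(X), dim(Y))) stop("X and Y must have identical shape")
  N <- nrow(X)
  if (N < 2) stop("FOSCTTM needs at least 2 cells")
  D <- cross_dist(X, Y)            # D[i, j] = d(x_i, y_j)
  true_d <- diag(D)
  n1 <- colSums(D < rep(true_d, each = N))   # j : d(x_j, y_i) < d(x_i, y_i)
  n2 <- rowSums(D < true_d)                  # j : d(x_i, y_j) < d(x_i, y_i)
  (sum(n1 / N) + sum(n2 / N)) / (2 * N)
}

#' k-nearest-neighbour label transfer
#'
#' Majority vote among the `k` Euclidean nearest reference cells; ties are
#' broken by the smallest cumulative neighbour distance, then by
#' lexicographic label order.
#'
#' @param reference Numeric matrix (or `latent_representation`) of
#'   reference embeddings.
#' @param ref_labels Character labels, one per reference row.
#' @param query Numeric matrix of query embeddings in the same space.
#' @param k Number of neighbours (`<= nrow(reference)`).
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_transfer <- function(reference, ref_labels, query, k = 5) {
  reference <- as_embedding(reference); query <- as_embedding(query)
  if (nrow(reference) == 0) stop("empty reference")
  if (length(ref_labels) != nrow(reference)) {
    stop("one label per reference row required")
  }
  if (k > nrow(reference)) stop("k exceeds reference size")
  ref_labels <- as.character(ref_labels)
  D <- cross_dist(query, reference)
  apply(D, 1, function(dr) {
    nn <- order(dr)[seq_len(k)]
    labs <- ref_labels[nn]
    votes <- table(labs)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      cum <- vapply(top, function(l) sum(dr[nn][labs == l]), 1)
      top <- top[cum == min(cum)]
      top <- sort(top)
    }
    top[1]
  })
}

#' Accuracy and macro-F1 of a label prediction
#'
#' Macro-F1 is the unweighted mean of per-class F1 over the classes present
#' in the true labels; a class never predicted contributes an F1 of 0.
#'
#' @param truth,pred Character vectors of equal length.
#' @return List with `accuracy` and `macro_f1`.
#' @export
classification_scores <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(pred)) stop("length mismatch")
  acc <- mean(truth == pred)
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1)
  list(accuracy = acc, macro_f1 = mean(f1))
}

#' Generation quality statistics
#'
#' Pearson and Spearman correlations are computed per feature across
#' cells; features that are constant in either matrix have undefined
#' correlation and are reported as 0 and flagged.  MSE/RMSE are over all
#' entries.
#'
#' @param pred,truth Numeric matrices of identical shape
#'   (cells x features).
#' @return List with `pearson_per_feature`, `spearman_per_feature`,
#'   `constant_features` (logical flag vector), `mse`, `rmse`.
#' @export
generation_scores <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  nf <- ncol(pred)
  pea <- numeric(nf); spe <- numeric(nf); const <- logical(nf)
  for (j in seq_len(nf)) {
    if (stats::sd(pred[, j]) == 0 || stats::sd(truth[, j]) == 0) {
      const[j] <- TRUE
    } else {
      pea[j] <- stats::cor(pred[, j], truth[, j])
      spe[j] <- stats::cor(pred[, j], truth[, j], method = "spearman")
    }
  }
  mse <- mean((pred - truth)^2)
  list(pearson_per_feature = pea, spearman_per_feature = spe,
       constant_features = const, mse = mse, rmse = sqrt(mse))
}

#' Assemble a full metrics report
#'
#' @param latent_a,latent_b Row-paired embeddings of the two modalities.
#' @param labels Optional per-cell labels; when given, cross-modality label
#'   transfer (reference = `latent_a`, query = `latent_b`) is scored.
#' @param pred,truth Optional generation output and measured target.
#' @param k Neighbours for label transfer.
#' @return List of class `metrics_report`.
#' @export
metrics_report <- function(latent_a, latent_b, labels = NULL,
                           pred = NULL, truth = NULL, k = 5) {
  rep <- list(foscttm = foscttm(latent_a, latent_b))
  if (!is.null(labels)) {
    pl <- knn_transfer(latent_a, labels, latent_b, k = k)
    cs <- classification_scores(labels, pl)
    rep$accuracy <- cs$accuracy
    rep$macro_f1 <- cs$macro_f1
  }
  if (!is.null(pred) && !is.null(truth)) {
    gs <- generation_scores(pred, truth)
    rep$pearson_per_feature <- gs$pearson_per_feature
    rep$spearman_per_feature <- gs$spearman_per_feature
    rep$mse <- gs$mse
    rep$rmse <- gs$rmse
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  foscttm   %.4f\n", x$foscttm))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy  %.4f\n  macro_f1  %.4f\n",
                x$accuracy, x$macro_f1))
  }
  if (!is.null(x$mse)) {
    cat(sprintf("  mse       %.4g (rmse %.4g), mean pearson %.4f\n",
                x$mse, x$rmse, mean(x$pearson_per_feature)))
  }
  invisible(x)
}
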