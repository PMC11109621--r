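#' @keywords internal
"_PACKAGE"

MODALITIES <- c("rna", "protein", "atac")
LAYERS <- c("raw", "normalized", "reduced")

#' Construct a single-modality expression matrix
#'
#' The basic container of the package: a dense cells x features matrix
#' together with unique cell and feature identifiers, a modality tag and a
#' processing-layer tag (`raw` counts, `normalized`, or `reduced` after
#' dimension alignment).
#'
#' @param values Numeric matrix, cells in rows, features in columns.
#' @param cell_ids Character vector of unique cell identifiers (one per row).
#' @param feature_ids Character vector of unique feature identifiers
#'   (one per column).
#' @param modality One of `"rna"`, `"protein"`, `"atac"`.
#' @param layer One of `"raw"`, `"normalized"`, `"reduced"`.
#' @return An object of class `modality_matrix`.
#' @export
modality_matrix <- function(values, cell_ids = rownames(values),
                            feature_ids = colnames(values),
                            modality = c("rna", "protein", "atac"),
                            layer = c("raw", "normalized", "reduced")) {
  modality <- match.arg(modality)
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(feature_ids)) {
    feature_ids <- paste0("feature_", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(values) != length(cell_ids)) {
    stop("row count (", nrow(values), ") != number of cell ids (",
         length(cell_ids), ")")
  }
  if (ncol(values) != length(feature_ids)) {
    stop("column count (", ncol(values), ") != number of feature ids (",
         length(feature_ids), ")")
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality, layer = layer),
    class = "modality_matrix"
  )
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix> %s [%s]: %d cells x %d features\n",
              x$modality, x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.modality_matrix <- function(x) dim(x$values)

#' Read one modality from disk
#'
#' Supports a MatrixMarket directory (`matrix.mtx` + `barcodes.tsv` +
#' `features.tsv`), a dense CSV/TSV with cells in rows, or an H5AD
#' container.  MTX triplets are stored either cells x features or
#' features x cells in the wild; the orientation is disambiguated against
#' the sidecar lengths and an error is raised when the matrix is square
#' and the sidecars cannot decide.
#'
#' H5AD is read by shelling out to the Python `anndata` library (an R-native
#' HDF5 reader is not assumed); `X`, `obs_names` and `var_names` are
#' converted to a temporary dense CSV first.
#'
#' @param path File (CSV/TSV/H5AD) or directory (MTX) to read.
#' @param format One of `"mtx_dir"`, `"csv"`, `"h5ad"`.
#' @param modality Modality tag for the returned matrix.
#' @return A raw-layer [modality_matrix()].
#' @export
read_modality <- function(path, format = c("mtx_dir", "csv", "h5ad"),
                          modality = c("rna", "protein", "atac")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("path does not exist: ", path)
  switch(format,
    mtx_dir = read_mtx_dir(path, modality),
    csv = read_dense_csv(path, modality),
    h5ad = read_h5ad(path, modality)
  )
}

read_mtx_dir <- function(path, modality) {
  mtx <- file.path(path, "matrix.mtx")
  bc <- file.path(path, "barcodes.tsv")
  ft <- file.path(path, "features.tsv")
  missing <- c(mtx, bc, ft)[!file.exists(c(mtx, bc, ft))]
  if (length(missing)) {
    stop("missing sidecar/matrix file(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- readLines(bc)
  features <- utils::read.delim(ft, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  nb <- length(barcodes); nf <- length(features)
  if (nrow(m) == nb && ncol(m) == nf) {
    if (nb == nf && nb > 1) {
      # square with equal sidecars: orientation genuinely ambiguous only if
      # the transposed reading would also fit, which it does; refuse.
      stop("ambiguous MTX orientation: square matrix with equal sidecar ",
           "lengths")
    }
  } else if (nrow(m) == nf && ncol(m) == nb) {
    m <- t(m)
  } else {
    stop(sprintf(
      "MTX dimensions %dx%d match neither %d barcodes x %d features nor its transpose",
      nrow(m), ncol(m), nb, nf))
  }
  modality_matrix(m, barcodes, features, modality = modality, layer = "raw")
}

read_dense_csv <- function(path, modality) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  modality_matrix(as.matrix(df), rownames(df), colnames(df),
                  modality = modality, layer = "raw")
}

read_h5ad <- function(path, modality) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("h5ad input requires a python interpreter with anndata")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  code <- paste(
    "import sys, anndata, numpy as np, pandas as pd",
    "a = anndata.read_h5ad(sys.argv[1])",
    "X = a.X.toarray() if hasattr(a.X, 'toarray') else np.asarray(a.X)",
    "pd.DataFrame(X, index=a.obs_names, columns=a.var_names).to_csv(sys.argv[2])",
    sep = "; ")
  status <- system2(py, c("-c", shQuote(code), shQuote(path), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(tmp)) {
    stop("failed to read h5ad via python/anndata: ",
         paste(status, collapse = " "))
  }
  read_dense_csv(tmp, modality)
}

#' Write a modality matrix to an MTX directory or CSV
#'
#' @param m A [modality_matrix()].
#' @param path Target directory (`mtx_dir`) or file (`csv`).
#' @param format Output format.
#' @return `path`, invisibly.
#' @export
write_modality <- function(m, path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "modality_matrix"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(m$values), path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
    utils::write.table(m$feature_ids, file.path(path, "features.tsv"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Pair modalities into a row-aligned multimodal dataset
#'
#' All modalities are brought to an identical cell order.  Under
#' `by_order` the matrices must already have equal cell counts and are
#' paired row-for-row; under `by_barcode` the intersection of cell ids is
#' taken and every modality reordered to it.
#'
#' @param datasets List of [modality_matrix()] objects (>= 1).
#' @param mode `"by_order"` (default) or `"by_barcode"`.
#' @param labels Optional per-cell character labels, in the cell order of
#'   the first modality.
#' @return An object of class `paired_dataset` with fields `modalities`
#'   (named by modality tag), `pairing` and `labels`.
#' @export
pair <- function(datasets, mode = c("by_order", "by_barcode"),
                 labels = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "modality_matrix")))
  tags <- vapply(datasets, `[[`, "", "modality")
  if (anyDuplicated(tags)) tags <- make.unique(tags)
  names(datasets) <- tags
  if (mode == "by_order") {
    ns <- vapply(datasets, function(d) nrow(d$values), 1L)
    if (length(unique(ns)) != 1) {
      stop("by_order pairing requires equal cell counts, got: ",
           paste(ns, collapse = ", "))
    }
  } else {
    common <- Reduce(intersect, lapply(datasets, `[[`, "cell_ids"))
    if (length(common) == 0) stop("empty barcode intersection")
    first_order <- datasets[[1]]$cell_ids
    common <- first_order[first_order %in% common]
    if (!is.null(labels)) {
      names(labels) <- datasets[[1]]$cell_ids
      labels <- unname(labels[common])
    }
    datasets <- lapply(datasets, function(d) {
      modality_matrix(d$values[common, , drop = FALSE], common,
                      d$feature_ids, modality = d$modality, layer = d$layer)
    })
  }
  if (!is.null(labels) &&
      length(labels) != nrow(datasets[[1]]$values)) {
    stop("labels length does not match paired cell count")
  }
  structure(list(modalities = datasets, pairing = mode,
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d modalities (%s), %d cells, pairing=%s\n",
              length(x$modalities),
              paste(names(x$modalities), collapse = ", "),
              nrow(x$modalities[[1]]$values), x$pairing))
  invisible(x)
}

n_cells <- function(ds) nrow(ds$modalities[[1]]$values)

# ---- model serialization ----------------------------------------------------
# Single JSON archive: config + every weight array with dims and hex-float
# ("%a") encoded values, so the round trip is bit-exact while the artifact
# stays plain text.

num_to_hex <- function(x) sprintf("%a", as.double(x))
hex_to_num <- function(h) as.numeric(h)

serialize_weights <- function(w) {
  if (is.list(w)) return(lapply(w, serialize_weights))
  list(dim = if (is.null(dim(w))) length(w) else dim(w),
       hex = num_to_hex(w))
}

deserialize_weights <- function(node) {
  if (!is.null(node$hex)) {
    x <- hex_to_num(unlist(node$hex))
    d <- unlist(node$dim)
    if (length(d) > 1) dim(x) <- d
    return(x)
  }
  lapply(node, deserialize_weights)
}

#' Save / load a trained model
#'
#' `save_model()` writes a single plain-text JSON archive holding the model
#' configuration and every weight array; floating-point values are stored
#' as C99 hex-float literals so that `load_model(save_model(m))` restores
#' them bit-for-bit and the forward pass is exactly reproducible.
#'
#' @param model A model object as returned by [train_integration()] or
#'   [train_generation()] (fields `weights`, `config`, `meta`).
#' @param path File path to write to / read from.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model object.
#' @export
save_model <- function(model, path) {
  stopifnot(is.list(model), !is.null(model$weights), !is.null(model$config))
  payload <- list(
    format = "scmformer-model-v1",
    config = unclass(model$config),
    meta = model$meta,
    weights = serialize_weights(model$weights)
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write model archive to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "scmformer-model-v1")) {
    stop("not a recognised model archive: ", path)
  }
  cfg_in <- lapply(payload$config, function(x) {
    if (is.list(x)) unlist(x) else x
  })
  cfg <- do.call(scm_config, cfg_in[names(cfg_in) %in%
                                      names(formals(scm_config))])
  weights <- deserialize_weights(payload$weights)
  model <- structure(list(weights = weights, config = cfg,
                          meta = payload$meta),
                     class = "scm_model")
  check_model_shapes(model)
  model
}

check_model_shapes <- function(model) {
  s <- model$config$s
  for (l in model$weights$layers) {
    if (!identical(dim(l$W_qkv), c(s, 3L * s))) {
      stop(sprintf("weight/config mismatch: W_qkv is %dx%d but config s=%d",
                   nrow(l$W_qkv), ncol(l$W_qkv), s))
    }
    if (!identical(dim(l$W1), c(s, 2L * s)) ||
        !identical(dim(l$W2), c(2L * s, s))) {
      stop("weight/config mismatch: feed-forward widths do not match s")
    }
  }
  if (ncol(model$weights$pos) != s) {
    stop("weight/config mismatch: positional table width != s")
  }
  invisible(model)
}
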