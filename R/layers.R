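#' Single-omics layer container
#'
#' Holds one modality's cell-by-feature matrix together with its feature
#' ids, per-cell batch labels and generative family: `"NB"` (negative
#' binomial; non-negative integer counts, e.g. RNA or ATAC) or `"ZILN"`
#' (zero-inflated log-normal; non-negative real levels, e.g. gene-body
#' methylation).
#'
#' @param X Cells-by-features matrix (dense or `Matrix` sparse).
#' @param features Character vector of feature ids (defaults to colnames).
#' @param family `"NB"` or `"ZILN"`.
#' @param name Layer name.
#' @param batches Optional per-cell batch labels (any vector; converted to
#'   dense integer codes 1..B).
#' @return An object of class `"omics_layer"`.
#' @export
omics_layer <- function(X, features = colnames(X), family = c("NB", "ZILN"),
                        name = "layer", batches = NULL) {
  family <- match.arg(family)
  if (is.null(features)) stop("omics_layer: feature ids are required")
  if (length(features) != ncol(X))
    stop("omics_layer: feature count does not match ncol(X)")
  if (anyDuplicated(features)) stop("omics_layer: duplicated feature ids")
  X <- as(as(X, "CsparseMatrix"), "generalMatrix")
  if (any(X@x < 0)) stop("omics_layer: values must be non-negative")
  if (family == "NB" && any(abs(X@x - round(X@x)) > 1e-8))
    stop("omics_layer: NB layers must contain integer counts")
  if (!all(is.finite(X@x))) stop("omics_layer: values must be finite")
  if (is.null(batches)) batches <- rep(1L, nrow(X))
  if (length(batches) != nrow(X))
    stop("omics_layer: batch labels must have one entry per cell")
  b <- as.integer(factor(batches))
  structure(list(name = name, X = X, features = as.character(features),
                 family = family, batches = b,
                 batch_levels = levels(factor(batches)),
                 reduced = NULL, reduction = NULL),
            class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("Omics layer '%s': %d cells x %d features, family %s, %d batch(es)%s\n",
              x$name, nrow(x$X), length(x$features), x$family,
              max(x$batches),
              if (is.null(x$reduced)) "" else
                sprintf(", reduced to %d dims (%s)", ncol(x$reduced),
                        x$reduction$method)))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$X)

# log1p counts-per-10k normalisation (dense result).
log1p_cpm <- function(X) {
  lib <- Matrix::rowSums(X)
  lib[lib == 0] <- 1
  log1p(as.matrix(X / lib * 1e4))
}

#' Linear dimensionality reduction front-end
#'
#' Fits the fixed first transformation layer of a data encoder: PCA on
#' log1p-CP10K values for expression-like layers, or LSI (TF-IDF followed
#' by truncated SVD, with the first component dropped when it correlates
#' > 0.9 with sequencing depth) for chromatin accessibility. The fitted
#' projection is stored on the layer and reapplied deterministically.
#'
#' @param layer An [omics_layer()].
#' @param r Number of reduced dimensions (clamped to the data rank).
#' @param method `"pca"` or `"lsi"`.
#' @return The layer with `reduced` (cells x r matrix) and `reduction`
#'   (the fitted projection) filled in.
#' @export
reduce_layer <- function(layer, r = 100, method = c("pca", "lsi")) {
  method <- match.arg(method)
  X <- layer$X
  r <- min(r, nrow(X) - 1L, ncol(X) - 1L)
  if (r < 1) stop("reduce_layer: not enough cells/features to reduce")
  if (method == "pca") {
    M <- if (layer$family == "NB") log1p_cpm(X) else log1p(as.matrix(X))
    ctr <- colMeans(M)
    pc <- prcomp(M, center = TRUE, scale. = FALSE, rank. = r)
    layer$reduced <- pc$x[, seq_len(r), drop = FALSE]
    layer$reduction <- list(method = "pca", center = ctr,
                            rotation = pc$rotation[, seq_len(r), drop = FALSE],
                            family = layer$family)
  } else {
    lib <- Matrix::rowSums(X); lib[lib == 0] <- 1
    idf <- log1p(nrow(X) / (1 + Matrix::colSums(X > 0)))
    M <- as.matrix(X / lib) %*% diag(idf, ncol(X))
    M <- log1p(M * 1e4)
    sv <- svd(M, nu = r + 1L, nv = r + 1L)
    comp <- sweep(sv$u[, seq_len(r + 1L), drop = FALSE], 2,
                  sv$d[seq_len(r + 1L)], `*`)
    drop1 <- abs(cor(comp[, 1], log(lib))) > 0.9
    keep <- if (drop1) 2:(r + 1L) else seq_len(r)
    layer$reduced <- comp[, keep, drop = FALSE]
    layer$reduction <- list(method = "lsi", idf = idf,
                            v = sv$v[, keep, drop = FALSE],
                            family = layer$family)
  }
  colnames(layer$reduced) <- paste0("dim", seq_len(ncol(layer$reduced)))
  layer
}

# Apply a fitted reduction to (possibly new) raw data.
apply_reduction <- function(red, X) {
  if (red$method == "pca") {
    M <- if (red$family == "NB") log1p_cpm(X) else log1p(as.matrix(X))
    sweep(M, 2, red$center) %*% red$rotation
  } else {
    lib <- Matrix::rowSums(X); lib[lib == 0] <- 1
    M <- as.matrix(X / lib) %*% diag(red$idf, ncol(X))
    log1p(M * 1e4) %*% red$v
  }
}
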