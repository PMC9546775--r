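# Cross-modal integration benchmark metrics. All metrics operate on
# plain embedding matrices plus label vectors and are checked against
# quadratic brute-force references in the test suite.

# Ordered K-nearest-neighbour indices under Euclidean distance, ties
# broken by index for determinism. Returns an N x K integer matrix.
knn_indices <- function(emb, K) {
  D <- as.matrix(dist(emb))
  diag(D) <- Inf
  K <- as.integer(K)
  nn <- vapply(seq_len(nrow(D)), function(i) order(D[i, ])[seq_len(K)],
               integer(K))
  if (is.matrix(nn)) t(nn) else matrix(nn, ncol = 1L)
}

default_K <- function(N) {
  K <- max(1, round(0.01 * N))
  as.integer(K)
}

#' Mean average precision of cell-type neighbourhoods
#'
#' For each cell, the average cell-type precision over its ordered
#' Euclidean K-nearest neighbours (up to each type-matched neighbour; 0
#' when no neighbour matches), averaged over cells. Higher is better
#' cell-type resolution.
#'
#' @param emb Cells x dims embedding matrix.
#' @param types Cell-type label per cell.
#' @param K Neighbourhood size; default 1% of the cell count (at least
#'   1).
#' @return A value in \[0, 1\].
#' @export
mean_average_precision <- function(emb, types, K = NULL) {
  N <- nrow(emb)
  K <- K %||% default_K(N)
  if (K < 1) { warning("K clamped to 1"); K <- 1L }
  nn <- knn_indices(emb, K)
  ap <- vapply(seq_len(N), function(i) {
    match_i <- types[nn[i, ]] == types[i]
    if (!any(match_i)) return(0)
    prec <- cumsum(match_i) / seq_len(K)
    sum(prec * match_i) / sum(match_i)
  }, 1)
  mean(ap)
}

# Silhouette widths with the standard conventions: singleton clusters
# and single-cluster inputs get width 0.
silhouette_widths <- function(emb, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) return(rep(0, nrow(emb)))
  sil <- cluster::silhouette(labels, dist(emb))
  out <- rep(0, nrow(emb))
  out[] <- sil[, "sil_width"]
  out
}

#' Cell-type average silhouette width, rescaled to \[0, 1\]
#'
#' `(mean silhouette + 1) / 2` with silhouettes computed on cell-type
#' labels under Euclidean distance. Higher is better cell-type
#' resolution.
#'
#' @inheritParams mean_average_precision
#' @return A value in \[0, 1\].
#' @export
cell_type_asw <- function(emb, types) {
  (mean(silhouette_widths(emb, types)) + 1) / 2
}

#' Neighbourhood consistency between two embeddings
#'
#' Mean Jaccard overlap between each cell's K-nearest-neighbour sets in
#' a single-omics embedding and in the integrated embedding; measures
#' how much per-layer variation the integration preserves.
#'
#' @param emb_single,emb_integrated Two embeddings of the same cells.
#' @param K Neighbourhood size; default 1% of cells.
#' @return A value in \[0, 1\].
#' @export
neighbor_consistency <- function(emb_single, emb_integrated, K = NULL) {
  stopifnot(nrow(emb_single) == nrow(emb_integrated))
  N <- nrow(emb_single)
  K <- K %||% default_K(N)
  nn1 <- knn_indices(emb_single, K)
  nn2 <- knn_indices(emb_integrated, K)
  mean(vapply(seq_len(N), function(i) {
    a <- nn1[i, ]; b <- nn2[i, ]
    length(intersect(a, b)) / length(union(a, b))
  }, 1))
}

# Min-max scale a vector across methods; degenerate ranges map to 0.5.
minmax_scale <- function(x) {
  r <- range(x)
  if (length(x) < 2 || r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Aggregate biology-conservation score across methods
#'
#' Min-max scales mean average precision, cell-type silhouette and
#' neighbour consistency across the compared methods, then averages the
#' three per method. With a single method (or zero range) a metric's
#' scaled value is defined as 0.5.
#'
#' @param map,asw,nc Numeric vectors, one entry per compared method.
#' @return Per-method scores in \[0, 1\].
#' @export
biology_conservation <- function(map, asw, nc) {
  (minmax_scale(map) + minmax_scale(asw) + minmax_scale(nc)) / 3
}

#' Seurat alignment score
#'
#' Layers are subsampled to the smallest layer's size (seeded), the mean
#' number of same-layer cells among each cell's K-nearest neighbours is
#' computed, and rescaled so that perfect mixing gives 1 and complete
#' separation gives 0.
#'
#' @param emb Cells x dims embedding.
#' @param layer Omics-layer label per cell.
#' @param K Neighbourhood size; default 1% of the subsampled cell count.
#' @param seed Subsampling seed.
#' @return A value in \[0, 1\] (clamped).
#' @export
seurat_alignment_score <- function(emb, layer, K = NULL, seed = 1) {
  layer <- as.factor(layer)
  n_min <- min(table(layer))
  keep <- with_seed(seed, {
    unlist(lapply(levels(layer), function(l) {
      idx <- which(layer == l)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
  })
  emb <- emb[keep, , drop = FALSE]
  lay <- layer[keep]
  N_layers <- nlevels(layer)
  K <- K %||% default_K(nrow(emb))
  nn <- knn_indices(emb, K)
  xbar <- mean(vapply(seq_len(nrow(emb)), function(i)
    sum(lay[nn[i, ]] == lay[i]), 1))
  sas <- 1 - (xbar - K / N_layers) / (K - K / N_layers)
  min(max(sas, 0), 1)
}

#' Omics-layer average silhouette width (mixing version)
#'
#' Within each cell type, computes silhouettes on the omics-layer labels
#' and averages `1 - |silhouette|`; the per-type values are then
#' averaged. 1 means the layers are indistinguishable within every cell
#' type. Single-layer input scores 1 by convention.
#'
#' @param emb Cells x dims embedding.
#' @param layer Omics-layer label per cell.
#' @param types Cell-type label per cell.
#' @return A value in \[0, 1\].
#' @export
omics_layer_asw <- function(emb, layer, types) {
  if (length(unique(layer)) < 2) return(1)
  vals <- vapply(unique(types), function(ty) {
    sel <- types == ty
    if (sum(sel) < 2) return(1)
    if (length(unique(layer[sel])) < 2) return(1)
    s <- silhouette_widths(emb[sel, , drop = FALSE], layer[sel])
    mean(1 - abs(s))
  }, 1)
  mean(vals)
}

#' Graph connectivity of cell types in the K-NN graph
#'
#' For each cell type, the fraction of its cells lying in the largest
#' connected component of the 15-nearest-neighbour graph restricted to
#' that type; averaged over types. Low values flag types split into
#' disconnected islands (poor mixing).
#'
#' @param emb Cells x dims embedding.
#' @param types Cell-type label per cell.
#' @param K_graph Neighbours in the graph (default 15).
#' @return A value in (0, 1\].
#' @export
graph_connectivity <- function(emb, types, K_graph = 15) {
  vals <- vapply(unique(types), function(ty) {
    sel <- which(types == ty)
    n <- length(sel)
    if (n == 1) return(1)
    kk <- min(K_graph, n - 1)
    nn <- knn_indices(emb[sel, , drop = FALSE], kk)
    g <- igraph::graph_from_edgelist(
      cbind(rep(seq_len(n), kk), as.vector(nn)), directed = FALSE)
    comp <- igraph::components(g)
    max(comp$csize) / n
  }, 1)
  mean(vals)
}

#' Aggregate omics-mixing score across methods
#'
#' Min-max scales the Seurat alignment score, omics-layer silhouette and
#' graph connectivity across methods, then averages the three.
#'
#' @param sas,olasw,gc Numeric vectors, one entry per compared method.
#' @return Per-method scores in \[0, 1\].
#' @export
omics_mixing <- function(sas, olasw, gc) {
  (minmax_scale(sas) + minmax_scale(olasw) + minmax_scale(gc)) / 3
}

#' Overall integration score
#'
#' Weighted combination `0.6 * biology conservation + 0.4 * omics
#' mixing`.
#'
#' @param bc,om Aggregate scores per method.
#' @return Per-method overall scores.
#' @export
overall_score <- function(bc, om) 0.6 * bc + 0.4 * om

#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' Single-cell alignment error between two embeddings with known
#' one-to-one cell pairing (row i of `emb_x` matches row i of `emb_y`):
#' the fraction of opposite-set cells strictly closer (Euclidean) than
#' the true match, averaged over cells and both directions. 0 means
#' perfect alignment; independent embeddings give about 0.5.
#'
#' @param emb_x,emb_y Paired embeddings, same number of rows.
#' @return A value in \[0, 1\].
#' @export
foscttm <- function(emb_x, emb_y) {
  stopifnot(nrow(emb_x) == nrow(emb_y))
  N <- nrow(emb_x)
  # full cross-distance matrix: d[i, j] = ||x_i - y_j||
  d2 <- outer(rowSums(emb_x^2), rowSums(emb_y^2), `+`) -
    2 * tcrossprod(emb_x, emb_y)
  d2 <- pmax(d2, 0)
  dtrue <- diag(d2)
  n1 <- vapply(seq_len(N), function(i) sum(d2[, i] < dtrue[i]), 1)
  n2 <- vapply(seq_len(N), function(i) sum(d2[i, ] < dtrue[i]), 1)
  (sum(n1 / N) + sum(n2 / N)) / (2 * N)
}

#' Feature-embedding consistency between two models
#'
#' Pearson correlation between the pairwise cosine similarities of a
#' random feature subsample under two feature-embedding matrices,
#' averaged over repeats. Rotation- and per-feature-scale-invariant.
#'
#' @param V_a,V_b Feature embeddings (features x dims) over the same
#'   feature set (rows aligned).
#' @param n_sub Features per subsample (clamped to the feature count).
#' @param n_rep Number of subsample repeats.
#' @param seed Integer seed.
#' @return A value in \[-1, 1\].
#' @export
feature_consistency <- function(V_a, V_b, n_sub = 2000, n_rep = 4,
                                seed = 1) {
  stopifnot(nrow(V_a) == nrow(V_b))
  nf <- nrow(V_a)
  n_sub <- min(n_sub, nf)
  with_seed(seed, {
    reps <- vapply(seq_len(n_rep), function(r) {
      sel <- sample.int(nf, n_sub)
      ca <- tcrossprod(l2_normalize_rows(V_a[sel, , drop = FALSE]))
      cb <- tcrossprod(l2_normalize_rows(V_b[sel, , drop = FALSE]))
      ut <- upper.tri(ca)
      cor(ca[ut], cb[ut])
    }, 1)
    mean(reps)
  })
}

#' Full benchmark metric report
#'
#' Convenience wrapper computing every per-method metric on one
#' embedding with layer and cell-type labels.
#'
#' @param emb Cells x dims integrated embedding.
#' @param layer Omics-layer label per cell.
#' @param types Cell-type label per cell.
#' @param emb_single Optional per-layer list of single-omics embeddings
#'   (same cells, layer-wise) for neighbour consistency.
#' @param seed Seed for the subsampled metrics.
#' @return Named list of metric values.
#' @export
metric_report <- function(emb, layer, types, emb_single = NULL, seed = 1) {
  out <- list(
    mean_average_precision = mean_average_precision(emb, types),
    cell_type_asw = cell_type_asw(emb, types),
    seurat_alignment_score = seurat_alignment_score(emb, layer, seed = seed),
    omics_layer_asw = omics_layer_asw(emb, layer, types),
    graph_connectivity = graph_connectivity(emb, types))
  if (!is.null(emb_single)) {
    nc <- mapply(function(es, l) {
      sel <- layer == l
      neighbor_consistency(es, emb[sel, , drop = FALSE])
    }, emb_single, unique(layer))
    out$neighbor_consistency <- mean(nc)
  }
  out
}
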