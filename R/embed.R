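# Downstream inference on the fitted model: embedding extraction,
# cosine regulatory scores with a shuffled-embedding permutation null,
# the integration consistency diagnostic, and k-NN label transfer.

#' Extract posterior-mean embeddings
#'
#' Deterministic posterior means of the cell embeddings (one matrix per
#' layer) and of the feature embeddings from a trained model. No
#' sampling is involved, so repeated calls are identical.
#'
#' @param model A fitted [glue_model()] (see [fit_glue()]).
#' @param layers Optional list of [omics_layer()] objects to encode
#'   (default: the layers the model was fitted on).
#' @return List with `cells` (named list of N_k x m matrices), `features`
#'   (vertices x m matrix with vertex-id rownames) and
#'   `fingerprint` (the model's guidance-graph fingerprint).
#' @export
get_embeddings <- function(model, layers = NULL) {
  if (!isTRUE(model$fitted))
    stop("get_embeddings: model has not been trained; call fit_glue()")
  layers <- layers %||% attr(model, "layers")
  cells <- list()
  for (k in seq_along(model$meta)) {
    ly <- layers[[k]]
    red <- if (!is.null(ly$reduced)) ly$reduced
      else apply_reduction(ly$reduction %||%
                             attr(model, "layers")[[k]]$reduction, ly$X)
    cells[[k]] <- encoder_forward(model, k, red)$mean
    rownames(cells[[k]]) <- rownames(ly$X)
  }
  names(cells) <- model$layer_names
  V <- graph_encoder_forward(model)$mean
  rownames(V) <- model$vertices
  list(cells = cells, features = V, fingerprint = model$graph_fingerprint)
}

#' Cosine regulatory scores for candidate feature pairs
#'
#' For each candidate pair, the cosine similarity between the two
#' features' embeddings, averaged across independently trained repeats.
#' Candidate pairs are restricted by the caller (typically peak--gene
#' pairs within 150 kb).
#'
#' @param V_repeats List of feature-embedding matrices (one per training
#'   repeat) with feature ids as rownames.
#' @param pairs Data.frame with columns `feature_i`, `feature_j` (and
#'   optionally extra columns such as `distance_kb`, carried through).
#' @return The `pairs` data.frame with a `score` column appended
#'   (`NA` with a warning for zero-norm embeddings).
#' @export
regulatory_scores <- function(V_repeats, pairs) {
  if (!is.list(V_repeats) || is.matrix(V_repeats))
    V_repeats <- list(V_repeats)
  stopifnot(length(V_repeats) >= 1)
  scores <- matrix(NA_real_, nrow(pairs), length(V_repeats))
  for (r in seq_along(V_repeats)) {
    V <- V_repeats[[r]]
    a <- V[as.character(pairs$feature_i), , drop = FALSE]
    b <- V[as.character(pairs$feature_j), , drop = FALSE]
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    bad <- na == 0 | nb == 0
    if (any(bad))
      warning("regulatory_scores: ", sum(bad),
              " pair(s) with zero-norm embeddings; score set to NA")
    s <- rowSums(a * b) / (na * nb)
    s[bad] <- NA_real_
    scores[, r] <- s
  }
  pairs$score <- rowMeans(scores)
  pairs
}

#' Permutation significance for regulatory scores
#'
#' Builds a null by randomly permuting the assignment of embedding
#' vectors to features (within each repeat, re-averaging across repeats
#' exactly as for the observed scores), computes one-sided empirical
#' p-values with the add-one correction
#' `p = (1 + #null >= observed) / (1 + n_null)`, and adjusts them with
#' the Benjamini-Hochberg procedure.
#'
#' @param scored Output of [regulatory_scores()] (must have `score`).
#' @param V_repeats The same embedding repeats used for scoring.
#' @param n_shuffles Number of shuffled-embedding draws (>= 100).
#' @param seed Integer seed; results are reproducible given it.
#' @param alternative `"greater"` (default; high scores extreme) or
#'   `"two.sided"` (extremeness in |score|).
#' @return `scored` with `p` and `q` columns appended.
#' @export
regulatory_significance <- function(scored, V_repeats, n_shuffles = 1000,
                                    seed = 1,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_shuffles < 100)
    stop("regulatory_significance: need at least 100 shuffles")
  if (!is.list(V_repeats) || is.matrix(V_repeats))
    V_repeats <- list(V_repeats)
  obs <- scored$score
  npair <- length(obs)
  with_seed(seed, {
    null_scores <- matrix(NA_real_, npair, n_shuffles)
    for (s in seq_len(n_shuffles)) {
      acc <- matrix(0, npair, length(V_repeats))
      for (r in seq_along(V_repeats)) {
        V <- V_repeats[[r]]
        Vp <- V[sample.int(nrow(V)), , drop = FALSE]
        rownames(Vp) <- rownames(V)
        a <- Vp[as.character(scored$feature_i), , drop = FALSE]
        b <- Vp[as.character(scored$feature_j), , drop = FALSE]
        acc[, r] <- rowSums(a * b) /
          (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
      }
      null_scores[, s] <- rowMeans(acc)
    }
    stat <- if (alternative == "greater") obs else abs(obs)
    nullstat <- if (alternative == "greater") null_scores
      else abs(null_scores)
    p <- vapply(seq_len(npair), function(i) {
      if (is.na(stat[i])) return(NA_real_)
      (1 + sum(nullstat[i, ] >= stat[i])) / (1 + n_shuffles)
    }, 1)
    scored$p <- p
    scored$q <- p.adjust(p, method = "BH")
    scored
  })
}

#' Integration consistency diagnostic
#'
#' Measures whether an integration is consistent with the guidance
#' graph: cells from all layers are jointly k-means clustered in the
#' aligned embedding space, each layer's cluster members are aggregated
#' into metacells (counts summed, levels averaged), and each cross-layer
#' guidance edge contributes the Spearman correlation of its two
#' features across the paired metacells. The score is the edge-weighted
#' average of the sign-corrected correlations. Values near 0 flag
#' over-integration of inconsistent datasets; matched data score
#' clearly positive.
#'
#' @param embeddings Per-layer list of cell embedding matrices.
#' @param layers Per-layer list of [omics_layer()] objects (raw data).
#' @param graph The [guidance_graph()] used (or any edge set of
#'   interest).
#' @param n_meta Number of joint k-means clusters (metacells).
#' @param seed Integer seed for k-means.
#' @param min_meta Minimum usable paired metacells (error below).
#' @return The consistency score (a scalar in \[-1, 1\]).
#' @export
integration_consistency <- function(embeddings, layers, graph,
                                    n_meta = 100, seed = 1,
                                    min_meta = 3) {
  K <- length(layers)
  stopifnot(K >= 2, length(embeddings) == K)
  all_emb <- do.call(rbind, embeddings)
  which_layer <- rep(seq_len(K), vapply(embeddings, nrow, 1L))
  n_meta <- min(n_meta, nrow(all_emb))
  with_seed(seed, {
    km <- kmeans(all_emb, centers = n_meta, nstart = 1, iter.max = 50)
  })
  cl <- km$cluster
  # per-layer metacell profiles over clusters present in that layer:
  # average cell profiles (summed counts scale with cluster size, which
  # would otherwise induce spurious positive cross-layer correlation)
  profiles <- list()
  for (k in seq_len(K)) {
    sel <- which_layer == k
    a <- cl[sel]
    Xk <- as.matrix(layers[[k]]$X)
    M <- rowsum(Xk, a) / as.vector(table(a))
    profiles[[k]] <- M # rownames are cluster ids present in layer k
  }
  feat_layer <- stats::setNames(rep(seq_len(K), vapply(layers, function(l)
    length(l$features), 1L)),
    unlist(lapply(layers, function(l) l$features)))
  ce <- cross_edges(graph)
  num <- 0; den <- 0; used <- 0
  for (t in seq_len(nrow(ce))) {
    ki <- feat_layer[ce$i[t]]; kj <- feat_layer[ce$j[t]]
    if (is.na(ki) || is.na(kj) || ki == kj) next
    common <- intersect(rownames(profiles[[ki]]), rownames(profiles[[kj]]))
    if (length(common) < min_meta) next
    xi <- profiles[[ki]][common, ce$i[t]]
    xj <- profiles[[kj]][common, ce$j[t]]
    rho <- if (sd(xi) == 0 || sd(xj) == 0) {
      warning("integration_consistency: zero-variance metacell profile; ",
              "edge correlation treated as 0")
      0
    } else suppressWarnings(cor(xi, xj, method = "spearman"))
    num <- num + ce$weight[t] * ce$sign[t] * rho
    den <- den + ce$weight[t]
    used <- used + 1
  }
  if (used == 0 || den == 0)
    stop("integration_consistency: fewer than ", min_meta,
         " usable paired metacells on every edge")
  num / den
}

#' Transfer labels by k-nearest-neighbour majority vote
#'
#' Assigns each query cell the majority label among its `k_nn`
#' Euclidean nearest reference cells in the shared embedding space,
#' breaking ties by the nearest neighbour's label.
#'
#' @param ref_emb Reference embedding matrix.
#' @param ref_labels Label per reference cell.
#' @param query_emb Query embedding matrix (same dimensionality).
#' @param k_nn Number of neighbours (default 5).
#' @return Character vector of transferred labels, one per query cell.
#' @export
transfer_labels <- function(ref_emb, ref_labels, query_emb, k_nn = 5) {
  if (is.null(dim(ref_emb)) || nrow(ref_emb) == 0)
    stop("transfer_labels: empty reference")
  stopifnot(k_nn >= 1, length(ref_labels) == nrow(ref_emb))
  k_nn <- min(k_nn, nrow(ref_emb))
  ref_labels <- as.character(ref_labels)
  d2 <- outer(rowSums(query_emb^2), rowSums(ref_emb^2), `+`) -
    2 * tcrossprod(query_emb, ref_emb)
  vapply(seq_len(nrow(query_emb)), function(i) {
    nn <- order(d2[i, ])[seq_len(k_nn)]
    votes <- table(ref_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else {
      # tie: first neighbour whose label is among the tied ones
      ref_labels[nn[ref_labels[nn] %in% top][1]]
    }
  }, "")
}
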