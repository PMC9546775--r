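# Brute-force reference implementations used as independent oracles for
# the vectorised metric and graph code. Deliberately naive (explicit
# loops, O(N^2) or worse) and kept free of any package internals.

oracle_knn <- function(emb, K) {
  N <- nrow(emb)
  t(vapply(seq_len(N), function(i) {
    d <- vapply(seq_len(N), function(j)
      sqrt(sum((emb[i, ] - emb[j, ])^2)), 1)
    d[i] <- Inf
    order(d)[seq_len(K)]
  }, integer(K)))
}

oracle_map <- function(emb, types, K) {
  nn <- oracle_knn(emb, K)
  aps <- numeric(nrow(emb))
  for (i in seq_len(nrow(emb))) {
    hits <- 0; s <- 0
    for (k in seq_len(K)) {
      if (types[nn[i, k]] == types[i]) {
        hits <- hits + 1
        s <- s + hits / k
      }
    }
    aps[i] <- if (hits > 0) s / hits else 0
  }
  mean(aps)
}

oracle_silhouette <- function(emb, labels) {
  N <- nrow(emb)
  D <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    D[i, j] <- sqrt(sum((emb[i, ] - emb[j, ])^2))
  s <- numeric(N)
  for (i in seq_len(N)) {
    own <- which(labels == labels[i] & seq_len(N) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(D[i, labels == l]), 1))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

oracle_foscttm <- function(x, y) {
  N <- nrow(x)
  n1 <- n2 <- numeric(N)
  for (i in seq_len(N)) {
    dtrue <- sqrt(sum((x[i, ] - y[i, ])^2))
    for (j in seq_len(N)) {
      if (sqrt(sum((x[j, ] - y[i, ])^2)) < dtrue) n1[i] <- n1[i] + 1
      if (sqrt(sum((x[i, ] - y[j, ])^2)) < dtrue) n2[i] <- n2[i] + 1
    }
  }
  (sum(n1 / N) + sum(n2 / N)) / (2 * N)
}

oracle_sas <- function(emb, layer, K, seed) {
  # same seeded subsample as the implementation so values are comparable
  layer <- as.factor(layer)
  n_min <- min(table(layer))
  keep <- omicbridge:::with_seed(seed, {
    unlist(lapply(levels(layer), function(l) {
      idx <- which(layer == l)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
  })
  emb <- emb[keep, , drop = FALSE]; lay <- layer[keep]
  nn <- oracle_knn(emb, K)
  xbar <- mean(vapply(seq_len(nrow(emb)), function(i)
    sum(lay[nn[i, ]] == lay[i]), 1))
  min(max(1 - (xbar - K / nlevels(layer)) / (K - K / nlevels(layer)), 0), 1)
}

oracle_graph_connectivity <- function(emb, types, K_graph) {
  vals <- vapply(unique(types), function(ty) {
    sel <- which(types == ty)
    n <- length(sel)
    if (n == 1) return(1)
    kk <- min(K_graph, n - 1)
    nn <- oracle_knn(emb[sel, , drop = FALSE], kk)
    # union-find over the undirected k-NN edges
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (i in seq_len(n)) for (j in nn[i, ]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    comp <- vapply(seq_len(n), find, 1L)
    max(table(comp)) / n
  }, 1)
  mean(vals)
}

# all-pairs interval overlap (half-open)
oracle_overlap_edges <- function(peaks, genes, upstream = 2000) {
  out <- NULL
  for (p in seq_len(nrow(peaks))) for (g in seq_len(nrow(genes))) {
    if (peaks$chrom[p] != genes$chrom[g]) next
    gs <- genes$start[g]; ge <- genes$end[g]
    if (genes$strand[g] == "-") {
      s <- gs; e <- ge + upstream
    } else {
      s <- max(0, gs - upstream); e <- ge
    }
    if (peaks$start[p] < e && peaks$end[p] > s)
      out <- rbind(out, data.frame(i = peaks$id[p], j = genes$id[g]))
  }
  out
}

oracle_window_edges <- function(peaks, genes, window_kb = 150,
                                exponent = 0.75, upstream = 2000) {
  out <- NULL
  for (p in seq_len(nrow(peaks))) for (g in seq_len(nrow(genes))) {
    if (peaks$chrom[p] != genes$chrom[g]) next
    if (genes$strand[g] == "-") {
      ps <- genes$end[g]; pe <- genes$end[g] + upstream
    } else {
      ps <- max(0, genes$start[g] - upstream); pe <- genes$start[g]
    }
    gap <- max(ps - peaks$end[p], peaks$start[p] - pe, 0)
    d <- gap / 1000
    if (d <= window_kb)
      out <- rbind(out, data.frame(i = peaks$id[p], j = genes$id[g],
                                   w = (d + 1)^(-exponent)))
  }
  out
}

# tiny deterministic embedding fixtures
rand_embedding <- function(n, m, seed) {
  omicbridge:::with_seed(seed, matrix(rnorm(n * m), n, m))
}

random_rotation <- function(m, seed) {
  omicbridge:::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(m * m), m)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# Wilcoxon-statistic AUROC of scores for positives vs negatives
score_auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# small simulated dataset reused by several test files
small_sim <- function(seed = 17) {
  simulate_multiomics(sim_config(
    n_types = 3, cells_per_type = 40, n_genes = 60, n_peaks = 90,
    m_true = 6, seed = seed))
}

fast_config <- function(seed = 1, ...) {
  defaults <- list(m = 6, hidden = 32, hidden_disc = 32,
                   hidden_graph = 32, r_reduce = 20, minibatch = 64,
                   anneal_iters = 150, patience_lr_iters = 80,
                   patience_stop_iters = 150, max_iters = 600,
                   seed = seed)
  do.call(glue_config, utils::modifyList(defaults, list(...)))
}
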