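test_that("all metrics match brute-force references on random instances", {
  for (rep in 1:6) {
    set.seed(100 + rep)
    N <- sample(20:50, 1)
    m <- sample(2:6, 1)
    emb <- matrix(rnorm(N * m), N)
    types <- sample(letters[1:4], N, replace = TRUE)
    layer <- sample(c("rna", "atac"), N, replace = TRUE)
    # make both labels have at least 2 groups with >= 2 members
    types[1:8] <- rep(c("a", "b"), each = 4)
    layer[1:8] <- rep(c("rna", "atac"), 4)
    K <- 5
    expect_equal(mean_average_precision(emb, types, K),
                 oracle_map(emb, types, K), tolerance = 1e-10)
    expect_equal(cell_type_asw(emb, types),
                 (mean(oracle_silhouette(emb, types)) + 1) / 2,
                 tolerance = 1e-10)
    emb2 <- matrix(rnorm(N * m), N)
    nn1 <- omicbridge:::knn_indices(emb, K)
    nn2 <- omicbridge:::knn_indices(emb2, K)
    jac <- mean(vapply(seq_len(N), function(i)
      length(intersect(nn1[i, ], nn2[i, ])) /
        length(union(nn1[i, ], nn2[i, ])), 1))
    expect_equal(neighbor_consistency(emb, emb2, K), jac,
                 tolerance = 1e-10)
    expect_equal(neighbor_consistency(emb, emb, K), 1)
    expect_equal(seurat_alignment_score(emb, layer, K, seed = 7),
                 oracle_sas(emb, layer, K, seed = 7), tolerance = 1e-10)
    ol_ref <- mean(vapply(unique(types), function(ty) {
      sel <- types == ty
      if (length(unique(layer[sel])) < 2) return(1)
      mean(1 - abs(oracle_silhouette(emb[sel, , drop = FALSE],
                                     layer[sel])))
    }, 1))
    expect_equal(omics_layer_asw(emb, layer, types), ol_ref,
                 tolerance = 1e-10)
    expect_equal(graph_connectivity(emb, types, 4),
                 oracle_graph_connectivity(emb, types, 4),
                 tolerance = 1e-10)
    half <- floor(N / 2)
    ex <- emb[seq_len(half), , drop = FALSE]
    ey <- emb2[seq_len(half), , drop = FALSE]
    expect_equal(foscttm(ex, ey), oracle_foscttm(ex, ey),
                 tolerance = 1e-10)
  }
})

test_that("FOSCTTM is calibrated: 0 for identical, ~0.5 for independent", {
  emb <- rand_embedding(120, 8, seed = 3)
  expect_identical(foscttm(emb, emb), 0)
  vals <- vapply(1:20, function(s) {
    x <- rand_embedding(500, 10, seed = 1000 + s)
    y <- rand_embedding(500, 10, seed = 2000 + s)
    foscttm(x, y)
  }, 1)
  expect_true(all(abs(vals - 0.5) < 0.05))
  # symmetric in its two arguments
  x <- rand_embedding(60, 5, seed = 4); y <- rand_embedding(60, 5, seed = 5)
  expect_equal(foscttm(x, y), foscttm(y, x), tolerance = 1e-12)
  # hand-checked 3-cell instance in 1-D
  ex <- matrix(c(0, 1, 4)); ey <- matrix(c(0.4, 1.1, 3.8))
  # n2: x1: d(x1,y1)=.4 -> none closer; x2: d=.1 none; x3: d=.2 none
  # n1: y1: d(x1,y1)=.4 -> x2 at .7 no; y2: x1 at 1.1? no wait
  expect_equal(foscttm(ex, ey), oracle_foscttm(ex, ey), tolerance = 1e-12)
})

test_that("rigid motions leave neighbourhood metrics unchanged", {
  set.seed(11)
  N <- 40; m <- 5
  emb <- matrix(rnorm(N * m), N)
  types <- sample(c("a", "b", "c"), N, replace = TRUE)
  layer <- rep(c("l1", "l2"), N / 2)
  Q <- random_rotation(m, seed = 2)
  moved <- emb %*% Q + matrix(rnorm(m), N, m, byrow = TRUE) * 0 + 3
  expect_equal(mean_average_precision(moved, types),
               mean_average_precision(emb, types), tolerance = 1e-9)
  expect_equal(seurat_alignment_score(moved, layer, seed = 1),
               seurat_alignment_score(emb, layer, seed = 1),
               tolerance = 1e-9)
  expect_equal(neighbor_consistency(moved, emb),
               1, tolerance = 1e-12)
})

test_that("separated vs mixed layouts hit the metric extremes", {
  set.seed(21)
  tight <- rbind(matrix(rnorm(40, 0, 0.01), 20),
                 matrix(rnorm(40, 10, 0.01), 20))
  types <- rep(c("a", "b"), each = 20)
  expect_gt(cell_type_asw(tight, types), 0.99)
  expect_equal(mean_average_precision(tight, types, K = 5), 1)
  # random labels: silhouette near 0 -> scaled ASW near 0.5
  rnd <- replicate(30, cell_type_asw(matrix(rnorm(60), 30),
                                     sample(c("a", "b"), 30, TRUE)))
  expect_lt(abs(mean(rnd) - 0.5), 0.07)
  # fully separated layers: SAS 0
  layer <- rep(c("x", "y"), each = 20)
  expect_equal(seurat_alignment_score(tight, layer, K = 5, seed = 1), 0)
  expect_lt(omics_layer_asw(tight, layer, rep("t", 40)), 0.05)
  # perfectly interleaved layers score high
  inter <- matrix(rnorm(80 * 4), 80)
  expect_gt(seurat_alignment_score(inter, rep(c("x", "y"), 40), seed = 1),
            0.85)
  expect_gt(omics_layer_asw(inter, rep(c("x", "y"), 40), rep("t", 80)),
            0.9)
  # type split into two distant equal blobs: connectivity 0.5
  split2 <- rbind(matrix(rnorm(20, 0, 0.01), 10),
                  matrix(rnorm(20, 50, 0.01), 10))
  expect_equal(graph_connectivity(split2, rep("t", 20), K_graph = 4), 0.5)
  expect_equal(graph_connectivity(tight, types, K_graph = 5), 1)
})

test_that("aggregation scores min-max scale and average as specified", {
  map <- c(0.9, 0.5, 0.7); asw <- c(0.8, 0.6, 0.6); nc <- c(0.5, 0.1, 0.3)
  bc <- biology_conservation(map, asw, nc)
  hand <- (c(1, 0, 0.5) + c(1, 0, 0) + c(1, 0, 0.5)) / 3
  expect_equal(bc, hand, tolerance = 1e-12)
  expect_equal(bc[1], 1)
  # degenerate single-method scaling
  expect_equal(biology_conservation(0.4, 0.9, 0.1), 0.5)
  expect_equal(omics_mixing(0.2, 0.2, 0.2), 0.5)
  # overall score identity on fuzzed inputs
  set.seed(9)
  for (i in 1:20) {
    bcv <- runif(4); omv <- runif(4)
    expect_equal(overall_score(bcv, omv), 0.6 * bcv + 0.4 * omv)
  }
  expect_equal(overall_score(1, 1), 1)
  expect_equal(overall_score(1, 0), 0.6)
  expect_equal(overall_score(0.5, 0.25), 0.4)
  # min-max scaling is idempotent on already-scaled inputs
  x <- c(0, 0.25, 1)
  expect_equal(omicbridge:::minmax_scale(omicbridge:::minmax_scale(x)),
               omicbridge:::minmax_scale(x))
})

test_that("feature consistency is invariant to rotation and scale", {
  V <- rand_embedding(80, 6, seed = 12)
  Q <- random_rotation(6, seed = 13)
  expect_equal(feature_consistency(V, V %*% Q, n_sub = 50), 1,
               tolerance = 1e-9)
  scaled <- V * runif(80, 0.2, 5)
  expect_equal(feature_consistency(V, scaled, n_sub = 50), 1,
               tolerance = 1e-9)
  indep <- rand_embedding(80, 6, seed = 14)
  expect_lt(abs(feature_consistency(V, indep, n_sub = 60, n_rep = 8)),
            0.15)
})

test_that("metrics stay inside their declared ranges on fuzzed inputs", {
  for (s in 1:10) {
    set.seed(300 + s)
    N <- sample(15:40, 1)
    emb <- matrix(rnorm(N * 3) * runif(1, 0.1, 10), N)
    ty <- sample(letters[1:3], N, replace = TRUE)
    la <- sample(c("p", "q"), N, replace = TRUE)
    vals <- c(mean_average_precision(emb, ty),
              cell_type_asw(emb, ty),
              seurat_alignment_score(emb, la, seed = s),
              omics_layer_asw(emb, la, ty),
              graph_connectivity(emb, ty))
    expect_true(all(vals >= 0 & vals <= 1))
    half <- floor(N / 2)
    f <- foscttm(emb[1:half, , drop = FALSE],
                 emb[half + (1:half), , drop = FALSE])
    expect_true(f >= 0 && f <= 1)
  }
})
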