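sim_tr <- small_sim(seed = 23)
mod_tr <- glue_model(sim_tr$layers, sim_tr$graph, fast_config(seed = 8))
layers_tr <- attr(mod_tr, "layers")

test_that("generator gradients match finite differences on a tiny model", {
  sim <- simulate_multiomics(sim_config(
    n_types = 2, cells_per_type = 6, n_genes = 8, n_peaks = 10,
    n_methyl = 6, m_true = 3, seed = 7))
  cfg <- glue_config(m = 3, hidden = 5, hidden_disc = 5, hidden_graph = 6,
                     r_reduce = 4, minibatch = 4, lam_d = 0.3, lam_g = 0.1,
                     seed = 11)
  mod <- glue_model(sim$layers, sim$graph, cfg)
  ctx <- omicbridge:::build_train_ctx(mod, attr(mod, "layers"))
  set.seed(42)
  idx <- lapply(ctx$N, function(n) 1:4)
  cw <- lapply(ctx$N, function(n) rep(1, n))
  eps_u <- lapply(seq_len(ctx$K), function(k) matrix(rnorm(4 * cfg$m), 4))
  epsV <- matrix(rnorm(length(mod$vertices) * cfg$m),
                 length(mod$vertices))
  mb <- omicbridge:::sample_graph_minibatch(mod, 30, 2)
  noise2 <- matrix(rnorm(4 * ctx$K * cfg$m, sd = 0.3), 4 * ctx$K)
  fb <- omicbridge:::gen_forward_backward(mod, ctx, idx, cw, eps_u, epsV,
                                          mb, noise2)
  pars <- list(enc = mod$params$enc, dec = mod$params$dec,
               gcn = mod$params$gcn)
  f <- function(p) {
    m2 <- mod
    m2$params$enc <- p$enc; m2$params$dec <- p$dec; m2$params$gcn <- p$gcn
    omicbridge:::gen_forward_backward(m2, ctx, idx, cw, eps_u, epsV, mb,
                                      noise2, want_grads = FALSE)$J
  }
  ng <- omicbridge:::numeric_grad(f, pars, h = 1e-5)
  fa <- omicbridge:::tree_flatten(fb$grads)
  fn <- omicbridge:::tree_flatten(ng)
  expect_lt(max(abs(fa - fn)), 1e-5 * max(1, max(abs(fn))))
})

test_that("discriminator gradients match finite differences", {
  set.seed(1)
  U <- matrix(rnorm(12 * mod_tr$config$m), 12)
  y <- rep(1:2, each = 6)
  w <- runif(12, 0.5, 2)
  d <- omicbridge:::disc_forward(mod_tr, U)
  g <- omicbridge:::disc_ce_grad(d$prob, y, w, 2)
  db <- omicbridge:::disc_backward(mod_tr, d, g$dlogits)
  f <- function(p) {
    m2 <- mod_tr; m2$params$disc <- p
    dd <- omicbridge:::disc_forward(m2, U)
    omicbridge:::disc_ce_grad(dd$prob, y, w, 2)$loss
  }
  ng <- omicbridge:::numeric_grad(f, mod_tr$params$disc)
  expect_lt(max(abs(omicbridge:::tree_flatten(db$grads) -
                      omicbridge:::tree_flatten(ng))), 1e-6)
})

test_that("discriminator loss hits its closed-form anchor points", {
  emb <- list(matrix(rnorm(20 * 6), 20), matrix(rnorm(30 * 6), 30))
  # uniform weights reproduce the unweighted cross entropy
  lu <- discriminator_loss(mod_tr, emb)
  p1 <- discriminate(mod_tr, emb[[1]]); p2 <- discriminate(mod_tr, emb[[2]])
  expect_equal(lu, -(mean(log(p1[, 1])) + mean(log(p2[, 2]))) / 2,
               tolerance = 1e-12)
  # duplicating every cell of one layer leaves the weighted loss intact
  embd <- list(rbind(emb[[1]], emb[[1]]), emb[[2]])
  wd <- list(rep(1, 40), rep(1, 30))
  expect_equal(discriminator_loss(mod_tr, embd, wd), lu, tolerance = 1e-12)
  # chance-level output gives log K
  K <- 2
  modc <- mod_tr
  modc$params$disc$out$W[] <- 0
  modc$params$disc$out$b[] <- 0
  expect_equal(discriminator_loss(modc, emb), log(K), tolerance = 1e-12)
  expect_error(discriminator_loss(mod_tr, emb[1]), "two layers")
})

test_that("data ELBO reduces to pure reconstruction without KL and is
           maximised by a perfect decoder on constant data", {
  ly <- layers_tr$rna
  e0 <- data_elbo(mod_tr, ly, cells = 1:10, kl_weight = 0, seed = 3)
  e1 <- data_elbo(mod_tr, ly, cells = 1:10, kl_weight = 1, seed = 3)
  expect_gt(e0, e1) # KL is positive
  # analytic NB maximum at mu = x for constant data
  nv <- 5
  X <- matrix(7L, 4, nv, dimnames = list(NULL, paste0("f", 1:nv)))
  theta <- rep(3, nv)
  best <- sum(nb_log_prob(X[1, ], rep(7, nv), theta))
  worse <- sum(nb_log_prob(X[1, ], rep(5, nv), theta))
  expect_gt(best, worse)
  grid <- seq(5, 9, by = 0.05)
  lls <- vapply(grid, function(mu)
    nb_log_prob(X[1, ], rep(mu, nv), theta), 1)
  expect_equal(grid[which.max(lls)], 7, tolerance = 0.051)
  # all-zero minibatch stays finite
  lyz <- layers_tr$rna
  lyz$X[1, ] <- 0
  lyz <- reduce_layer(lyz, r = 20, method = "pca")
  mz <- glue_model(list(rna = lyz, atac = layers_tr$atac), sim_tr$graph,
                   fast_config(seed = 2))
  ez <- data_elbo(mz, attr(mz, "layers")$rna, cells = 1, seed = 1)
  expect_true(is.finite(ez))
})

test_that("graph ELBO equals its likelihood minus KL decomposition", {
  ge <- graph_elbo(mod_tr, n_edges = 500, n_neg = 1, seed = 9)
  gf <- omicbridge:::graph_encoder_forward(mod_tr)
  set.seed(9) # same stream as graph_elbo's with_seed
  epsV <- matrix(rnorm(length(gf$mean)), nrow(gf$mean))
  V <- gf$mean + exp(gf$logvar / 2) * epsV
  ll <- graph_log_likelihood(mod_tr, V, n_edges = 500, n_neg = 1, seed = 9)
  # the ll call redraws the minibatch under the same seed after the eps
  # draw; reproduce that stream: with_seed(9){eps; mb} vs with_seed(9){mb}
  kl <- sum(kl_diag_normal(gf$mean, gf$logvar))
  expect_lt(ge, ll) # KL > 0 pulls the bound below the likelihood term
  expect_equal(graph_elbo(mod_tr, n_edges = 500, seed = 5),
               graph_elbo(mod_tr, n_edges = 500, seed = 5))
})

test_that("balancing weights follow the cluster-matching formula exactly", {
  # two layers, one cluster each, identical centroids, sizes 10 and 40
  e1 <- matrix(rep(c(1, 0), each = 10), 10)
  e2 <- matrix(rep(c(1, 0), each = 40), 40)
  cw <- omicbridge:::compute_cluster_weights(
    list(e1, e2), list(rep(1L, 10), rep(1L, 40)))
  expect_equal(cw[[1]], 1 / 10)
  expect_equal(cw[[2]], 1 / 40)
  # cosine below threshold contributes zero (floor applies)
  a <- c(1, 0); b <- c(0.4 / sqrt(0.4^2 + 1), 1 / sqrt(0.4^2 + 1))
  expect_lt(sum(a * b), 0.5)
  e3 <- matrix(rep(b, each = 5), 5, byrow = FALSE)
  e3 <- matrix(b, 5, 2, byrow = TRUE)
  cw2 <- omicbridge:::compute_cluster_weights(
    list(matrix(a, 6, 2, byrow = TRUE), e3),
    list(rep(1L, 6), rep(1L, 5)), weight_floor = 1e-4)
  expect_equal(cw2[[1]], 1e-4)
  expect_equal(cw2[[2]], 1e-4)
  # three-layer toy against direct evaluation
  set.seed(77)
  embs <- lapply(c(12, 18, 9), function(n) matrix(rnorm(n * 4), n))
  cls <- lapply(embs, function(e) sample(1:2, nrow(e), replace = TRUE))
  cw3 <- omicbridge:::compute_cluster_weights(embs, cls)
  cents <- lapply(1:3, function(k)
    rowsum(embs[[k]], cls[[k]]) / as.vector(table(cls[[k]])))
  for (k in 1:3) for (i in 1:2) {
    f_sum <- 0
    for (k2 in setdiff(1:3, k)) for (j in 1:2) {
      cs <- sum(cents[[k]][i, ] * cents[[k2]][j, ]) /
        (sqrt(sum(cents[[k]][i, ]^2)) * sqrt(sum(cents[[k2]][j, ]^2)))
      if (cs > 0.5) f_sum <- f_sum + cs^4
    }
    w_ref <- f_sum / sum(cls[[k]] == i)
    if (w_ref == 0) w_ref <- 1e-4
    expect_equal(cw3[[k]][i], w_ref, tolerance = 1e-12)
  }
})

test_that("estimate_balancing_weights is reproducible and near-uniform on
           balanced layers", {
  set.seed(5)
  base <- matrix(rnorm(60 * 4), 60)
  embs <- list(base + rnorm(240, sd = 0.05),
               base + rnorm(240, sd = 0.05))
  b1 <- estimate_balancing_weights(embs, seed = 3)
  b2 <- estimate_balancing_weights(embs, seed = 3)
  expect_identical(b1$weights, b2$weights)
  expect_true(all(unlist(b1$weights) > 0))
})

test_that("a training step leaves the discriminator untouched at lam_d = 0
           and is deterministic given the seed", {
  cfg0 <- fast_config(seed = 3, lam_d = 0)
  mod0 <- glue_model(sim_tr$layers, sim_tr$graph, cfg0)
  st <- train_step(mod0, attr(mod0, "layers"), tau = 0, seed = 12)
  # with a zero adversarial weight the discriminator receives zero
  # gradient and its parameters stay bit-identical
  expect_identical(st$model$params$disc, mod0$params$disc)
  st2 <- train_step(mod0, attr(mod0, "layers"), tau = 0, seed = 12)
  expect_identical(st$model$params$enc, st2$model$params$enc)
  expect_identical(st$losses, st2$losses)
  # tau = 0 path adds no noise: repeated runs with equal seed identical
  st3 <- train_step(mod0, attr(mod0, "layers"), tau = 0, seed = 13)
  expect_false(identical(st$model$params$enc, st3$model$params$enc))
})

test_that("metacell aggregation conserves counts and matches brute-force
           assignment", {
  ly <- reduce_layer(sim_tr$layers$rna, r = 10, method = "pca")
  agg <- aggregate_metacells(ly, k = 12, seed = 4)
  expect_equal(sum(agg$layer$X), sum(ly$X))
  expect_identical(length(agg$assignment), nrow(ly$X))
  # averaged reduced coordinates per cluster
  expect_equal(unname(as.matrix(agg$layer$reduced)),
               unname(rowsum(ly$reduced, agg$assignment) /
                        as.vector(table(agg$assignment))),
               tolerance = 1e-10)
  # identity aggregation at k = N on well-separated points
  small <- omics_layer(matrix(rpois(5 * 30, 20), 5,
                              dimnames = list(NULL, paste0("f", 1:30))),
                       family = "NB")
  small <- reduce_layer(small, r = 3, method = "pca")
  ag2 <- aggregate_metacells(small, k = 5, seed = 1)
  expect_equal(sort(as.vector(rowSums(ag2$layer$X))),
               sort(as.vector(rowSums(small$X))))
  # ZILN layers average instead of summing
  lz <- omics_layer(matrix(runif(40 * 6), 40,
                           dimnames = list(NULL, paste0("s", 1:6))),
                    family = "ZILN")
  lz <- reduce_layer(lz, r = 3, method = "pca")
  agz <- aggregate_metacells(lz, k = 8, seed = 2)
  expect_equal(unname(as.matrix(agz$layer$X)),
               unname(rowsum(as.matrix(lz$X), agz$assignment) /
                        as.vector(table(agz$assignment))),
               tolerance = 1e-10)
})
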