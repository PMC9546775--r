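sim_fix <- small_sim()
mod_fix <- glue_model(sim_fix$layers, sim_fix$graph, fast_config(seed = 4))
layers_fix <- attr(mod_fix, "layers")

test_that("NB decoder conserves the library size exactly", {
  set.seed(2)
  m <- 6; nv <- 40
  V <- matrix(rnorm(nv * m), nv)
  dec <- list(logalpha = matrix(rnorm(nv), 1), beta = matrix(rnorm(nv), 1),
              logtheta = matrix(0, 1, nv))
  for (total in c(1, 537, 1e5)) {
    mu <- nb_decode(rnorm(m), V, dec, batch = 1, total = total)
    expect_equal(sum(mu), total, tolerance = 1e-12)
    expect_true(all(mu > 0))
  }
  # fuzzed batch of cells
  U <- matrix(rnorm(30 * m), 30)
  tot <- runif(30, 1, 1e4)
  mu <- nb_decode(U, V, dec, batch = 1, tot)
  expect_equal(rowSums(mu), tot, tolerance = 1e-9)
  expect_error(nb_decode(rnorm(m), V, dec, 1, 0), "positive")
})

test_that("NB decoder with null scaling gives the uniform mean", {
  m <- 4; nv <- 10
  V <- matrix(rnorm(nv * m), nv)
  dec <- list(logalpha = matrix(-Inf, 1, nv), beta = matrix(0, 1, nv),
              logtheta = matrix(0, 1, nv))
  mu <- nb_decode(rnorm(m), V, dec, 1, total = 100)
  expect_equal(unname(mu), rep(10, nv), tolerance = 1e-12)
})

test_that("batch-specific decoder parameters change the decoded mean", {
  set.seed(3)
  m <- 5; nv <- 12
  V <- matrix(rnorm(nv * m), nv)
  dec <- list(logalpha = rbind(rep(0, nv), rnorm(nv)),
              beta = rbind(rep(0, nv), rnorm(nv)),
              logtheta = matrix(0, 2, nv))
  u <- rnorm(m)
  mu1 <- nb_decode(u, V, dec, 1, 1000)
  mu2 <- nb_decode(u, V, dec, 2, 1000)
  expect_gt(max(abs(mu1 - mu2)), 1e-3)
  # ZILN decoder: affine map, no normalisation
  zdec <- list(logalpha = matrix(0, 1, nv), beta = matrix(2, 1, nv))
  expect_equal(unname(ziln_decode(rep(0, m), V, zdec, 1)), rep(2, nv))
  zdec2 <- list(logalpha = matrix(0, 1, nv),
                beta = matrix(0, 1, nv))
  expect_equal(unname(ziln_decode(u, V, zdec2, 1)),
               unname(as.vector(V %*% u)), tolerance = 1e-12)
})

test_that("cell encoder is deterministic with positive variance", {
  red <- layers_fix$rna$reduced[1:5, , drop = FALSE]
  e1 <- omicbridge:::encoder_forward(mod_fix, 1, red)
  e2 <- omicbridge:::encoder_forward(mod_fix, 1, red)
  expect_identical(e1$mean, e2$mean)
  expect_true(all(exp(e1$logvar) > 0))
  # identical cells give identical posteriors
  red2 <- red[c(1, 1), , drop = FALSE]
  e3 <- omicbridge:::encoder_forward(mod_fix, 1, red2)
  expect_equal(e3$mean[1, ], e3$mean[2, ])
  # all-zero cell stays finite
  ly0 <- layers_fix$rna
  z <- omicbridge:::apply_reduction(ly0$reduction,
                                    Matrix::Matrix(0, 1, ncol(ly0$X)))
  e0 <- omicbridge:::encoder_forward(mod_fix, 1, z)
  expect_true(all(is.finite(e0$mean)) && all(is.finite(e0$logvar)))
})

test_that("graph encoder is equivariant to vertex relabeling", {
  g <- sim_fix$graph
  cfg <- fast_config(seed = 9)
  mod <- glue_model(sim_fix$layers, g, cfg)
  gf <- omicbridge:::graph_encoder_forward(mod)
  # permute the vertex order of the graph; rebuild with the same
  # parameters re-indexed, outputs must permute identically
  set.seed(31)
  perm <- sample(nrow(g$vertices))
  g2 <- g
  g2$vertices <- g$vertices[perm, , drop = FALSE]
  mod2 <- glue_model(sim_fix$layers, g2, cfg)
  pmap <- match(mod2$vertices, mod$vertices)
  mod2$params$gcn <- mod$params$gcn
  mod2$params$gcn$W1 <- mod$params$gcn$W1[pmap, , drop = FALSE]
  gf2 <- omicbridge:::graph_encoder_forward(mod2)
  expect_equal(gf2$mean, gf$mean[pmap, , drop = FALSE], tolerance = 1e-10)
  expect_true(all(exp(gf$logvar) > 0))
})

test_that("isolated vertices with equal inputs get identical posteriors", {
  set.seed(6)
  ly <- omics_layer(matrix(rpois(60, 5), 20,
                           dimnames = list(NULL, c("x", "y", "z"))),
                    family = "NB", name = "rna")
  g2 <- guidance_graph(c("x", "y", "z"), NULL) # self-loops only
  mod2 <- glue_model(list(rna = ly), g2,
                     glue_config(m = 3, hidden = 8, hidden_disc = 8,
                                 hidden_graph = 8, r_reduce = 2, seed = 1))
  # two isolated vertices whose learnable input rows coincide
  mod2$params$gcn$W1[2, ] <- mod2$params$gcn$W1[1, ]
  gf <- omicbridge:::graph_encoder_forward(mod2)
  expect_equal(gf$mean[1, ], gf$mean[2, ], tolerance = 1e-12)
})

test_that("discriminator outputs valid probabilities", {
  U <- matrix(rnorm(10 * mod_fix$config$m), 10)
  p <- discriminate(mod_fix, U)
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-12)
  expect_true(all(p > 0 & p < 1))
  p1 <- discriminate(mod_fix, U[1, ])
  expect_equal(unname(p1), unname(p[1, ]))
})

test_that("graph likelihood respects sign semantics and its estimator
           matches exhaustive enumeration on a tiny graph", {
  # 4 vertices, one positive and one negative edge
  g <- guidance_graph(
    letters[1:4],
    data.frame(i = c("a", "c"), j = c("b", "d"), sign = c(1, -1),
               weight = c(1, 1)))
  ly <- omics_layer(matrix(rpois(40, 3), 10,
                           dimnames = list(NULL, letters[1:4])),
                    family = "NB")
  mod <- glue_model(list(rna = ly), g,
                    glue_config(m = 2, hidden = 4, hidden_disc = 4,
                                hidden_graph = 4, r_reduce = 2, seed = 2))
  big <- 50
  V <- rbind(c(big, 0), c(big, 0), c(0, big), c(0, big))
  # aligned positive edge saturates toward 0; aligned negative edge is
  # strongly penalised
  ed <- mod$edges
  pos_idx <- which(ed$sign == 1 & ed$i != ed$j)
  neg_idx <- which(ed$sign == -1)
  zp <- sum(V[ed$i[pos_idx], ] * V[ed$j[pos_idx], ])
  expect_gt(omicbridge:::log_sigmoid(1 * zp), -1e-100)
  expect_lt(omicbridge:::log_sigmoid(-1 * sum(V[ed$i[neg_idx], ] *
                                                V[ed$j[neg_idx], ])),
            -1000)
  # Monte-Carlo estimate converges to the exhaustive expectation
  set.seed(8)
  Vr <- matrix(rnorm(8, sd = 0.8), 4)
  est <- graph_log_likelihood(mod, Vr, n_edges = 40000, n_neg = 1,
                              seed = 3)
  # closed form: edges sampled prop. to weight (6 edges: 2 cross + 4
  # loops); negatives uniform over non-adjacent vertices
  ed <- mod$edges
  w <- ed$weight / sum(ed$weight)
  exp_term <- 0
  for (t in seq_along(ed$i)) {
    i <- ed$i[t]; j <- ed$j[t]; s <- ed$sign[t]
    pos <- omicbridge:::log_sigmoid(s * sum(Vr[i, ] * Vr[j, ]))
    nonadj <- setdiff(1:4, ed$adj[[i]])
    neg <- mean(vapply(nonadj, function(jp)
      omicbridge:::log_sigmoid(-s * sum(Vr[i, ] * Vr[jp, ])), 1))
    exp_term <- exp_term + w[t] * (pos + neg)
  }
  expect_equal(est, exp_term, tolerance = 0.02)
  # determinism given seed
  expect_identical(graph_log_likelihood(mod, Vr, seed = 5),
                   graph_log_likelihood(mod, Vr, seed = 5))
})

test_that("models refuse layers with features missing from the graph", {
  ly <- omics_layer(matrix(rpois(20, 2), 5,
                           dimnames = list(NULL, paste0("f", 1:4))),
                    family = "NB")
  g <- guidance_graph(paste0("f", 1:3), NULL)
  expect_error(glue_model(list(x = ly), g,
                          glue_config(m = 2, hidden = 4, hidden_disc = 4,
                                      hidden_graph = 4, r_reduce = 2)),
               "absent from")
})
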