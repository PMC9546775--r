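# Training engine: loss evaluation, the two-step adversarial RMSprop
# iteration (discriminator step, then autoencoder step), the two-stage
# procedure with discriminator noise annealing and cell-specific
# balancing weights, and validation-driven scheduling.

# ---- training context ----------------------------------------------------

# Precomputed per-layer tensors reused across iterations.
build_train_ctx <- function(model, layers) {
  K <- length(model$meta)
  ctx <- list(K = K, X = list(), Xred = list(), batches = list(),
              totals = list(), N = integer(K))
  for (k in seq_len(K)) {
    ly <- layers[[k]]
    if (is.null(ly$reduced))
      stop("training context: layer '", ly$name, "' has no fitted reduction")
    # densify moderate matrices once instead of per minibatch
    ctx$X[[k]] <- if (prod(dim(ly$X)) < 2e7) as.matrix(ly$X) else ly$X
    ctx$Xred[[k]] <- ly$reduced
    ctx$batches[[k]] <- ly$batches
    ctx$totals[[k]] <- pmax(Matrix::rowSums(ly$X), 1e-8)
    # per-cell sum of lgamma(x + 1): a data constant of the NB likelihood
    if (ly$family == "NB")
      ctx$lgx1[[k]] <- Matrix::rowSums(lgamma(ly$X + 1))
    ctx$N[k] <- nrow(ly$X)
  }
  ctx
}

# ---- exported loss evaluations ------------------------------------------

#' Data evidence lower bound for one layer
#'
#' Reconstruction log-likelihood (negative binomial or zero-inflated
#' log-normal, dispatched on the layer family) minus the KL divergence of
#' the cell posterior from the standard-normal prior, averaged over the
#' given cells.
#'
#' @param model A [glue_model()].
#' @param layer An [omics_layer()] matching one of the model's layers.
#' @param cells Optional integer vector of cell indices (default: all).
#' @param u Optional cells x m embedding matrix to decode from; by
#'   default one reparameterised posterior sample is drawn.
#' @param V Optional feature embedding matrix (vertices x m); by default
#'   one posterior sample is drawn.
#' @param kl_weight Scale on the KL term (0 gives pure reconstruction).
#' @param seed Seed for the posterior samples.
#' @return Mean per-cell evidence lower bound (a scalar).
#' @export
data_elbo <- function(model, layer, cells = NULL, u = NULL, V = NULL,
                      kl_weight = 1, seed = 1) {
  k <- match(layer$name, model$layer_names)
  if (is.na(k)) stop("data_elbo: layer '", layer$name, "' not in model")
  mt <- model$meta[[k]]
  if (layer$family != mt$family) stop("data_elbo: family mismatch")
  cells <- cells %||% seq_len(nrow(layer$X))
  if (is.null(layer$reduced))
    stop("data_elbo: layer has no fitted reduction")
  with_seed(seed, {
    enc <- encoder_forward(model, k, layer$reduced[cells, , drop = FALSE])
    klu <- kl_diag_normal(enc$mean, enc$logvar)
    if (is.null(u)) {
      eps <- matrix(rnorm(length(enc$mean)), nrow(enc$mean))
      u <- enc$mean + exp(enc$logvar / 2) * eps
    }
    if (is.null(V)) {
      gf <- graph_encoder_forward(model)
      epsV <- matrix(rnorm(length(gf$mean)), nrow(gf$mean))
      V <- gf$mean + exp(gf$logvar / 2) * epsV
    }
    Vk <- V[mt$vidx, , drop = FALSE]
    Xb <- as.matrix(layer$X[cells, , drop = FALSE])
    bb <- layer$batches[cells]
    dec <- model$params$dec[[k]]
    ll <- if (mt$family == "NB") {
      tot <- pmax(rowSums(Xb), 1e-8)
      mu <- nb_decode(u, Vk, dec, bb, tot)
      if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
      theta <- exp(dec$logtheta)[bb, , drop = FALSE]
      rowSums(nb_log_prob(Xb, mu, theta, sum = FALSE))
    } else {
      muz <- ziln_decode(u, Vk, dec, bb)
      if (is.null(dim(muz))) muz <- matrix(muz, nrow = 1)
      sig <- exp(dec$logsigma)[bb, , drop = FALSE]
      del <- sigmoid(dec$logitdelta)[bb, , drop = FALSE]
      rowSums(ziln_log_prob(Xb, muz, sig, del, sum = FALSE))
    }
    mean(ll - kl_weight * klu)
  })
}

#' Graph evidence lower bound
#'
#' [graph_log_likelihood()] of a reparameterised posterior sample of the
#' feature embeddings, minus the summed KL divergence of the per-vertex
#' posteriors from the standard-normal prior.
#'
#' @inheritParams graph_log_likelihood
#' @return A scalar.
#' @export
graph_elbo <- function(model, n_edges = NULL, n_neg = 1, seed = 1) {
  gf <- graph_encoder_forward(model)
  with_seed(seed, {
    epsV <- matrix(rnorm(length(gf$mean)), nrow(gf$mean))
    V <- gf$mean + exp(gf$logvar / 2) * epsV
    n_edges <- n_edges %||% length(model$edges$i)
    mb <- sample_graph_minibatch(model, n_edges, n_neg)
    graph_ll_core(model, V, mb)$ll - sum(kl_diag_normal(gf$mean, gf$logvar))
  })
}

#' Weighted discriminator loss
#'
#' Multiclass cross entropy of the omics-layer discriminator on per-layer
#' cell embeddings, with optional cell-specific balancing weights:
#' `-(1/K) sum_k (1/W_k) sum_n w_n log D_k(u_n)` where `W_k` is the
#' per-layer weight sum. With uniform weights this reduces to the plain
#' cross entropy; a chance-level discriminator on K layers gives
#' `log K`.
#'
#' @param model A [glue_model()].
#' @param embeddings List of per-layer embedding matrices (cells x m).
#' @param weights Optional list of per-cell positive weights, matching
#'   `embeddings`.
#' @return The weighted cross-entropy loss (a scalar).
#' @export
discriminator_loss <- function(model, embeddings, weights = NULL) {
  K <- length(embeddings)
  if (K < 2) stop("discriminator_loss: need at least two layers")
  if (is.null(weights))
    weights <- lapply(embeddings, function(e) rep(1, nrow(e)))
  loss <- 0
  for (k in seq_len(K)) {
    w <- weights[[k]]
    if (any(w <= 0)) stop("discriminator_loss: weights must be positive")
    Wk <- sum(w)
    if (Wk == 0) stop("discriminator_loss: zero weight normaliser")
    p <- disc_forward(model, embeddings[[k]])$prob
    loss <- loss - sum(w * log(pmax(p[, k], 1e-300))) / (K * Wk)
  }
  loss
}

# ---- the two-step adversarial iteration ---------------------------------

# Weighted-CE gradient wrt discriminator logits. y: layer index per row.
disc_ce_grad <- function(prob, y, w, K) {
  # loss = -(1/K) sum_k (1/W_k) sum_{n in k} w_n log p_{n,k}
  coef <- numeric(length(y))
  for (k in unique(y)) {
    sel <- y == k
    coef[sel] <- w[sel] / (K * sum(w[sel]))
  }
  Y <- matrix(0, nrow(prob), ncol(prob))
  Y[cbind(seq_along(y), y)] <- 1
  list(loss = -sum(coef * log(pmax(prob[cbind(seq_along(y), y)], 1e-300))),
       dlogits = coef * (prob - Y))
}

# Generator-side objective and gradients on a fixed minibatch with fixed
# reparameterisation draws, edge sample and discriminator noise: a pure
# function of the encoder/decoder/GCN parameters, which makes the
# hand-derived gradients directly checkable against finite differences.
# The objective maximised is
#   J = lam_d L_D + lam_g K L_G + sum_k L_Xk.
gen_forward_backward <- function(model, ctx, idx, cell_w, eps_u, epsV,
                                 mb, noise2, want_grads = TRUE,
                                 enc_cache = NULL, gf_cache = NULL) {
  cfg <- model$config
  K <- ctx$K

  enc_fwd <- list(); U <- list()
  for (k in seq_len(K)) {
    ef <- enc_cache[[k]] %||%
      encoder_forward(model, k, ctx$Xred[[k]][idx[[k]], , drop = FALSE])
    U[[k]] <- ef$mean + exp(ef$logvar / 2) * eps_u[[k]]
    enc_fwd[[k]] <- ef
  }
  gf <- gf_cache %||% graph_encoder_forward(model)
  V <- gf$mean + exp(gf$logvar / 2) * epsV

  Uall <- do.call(rbind, U)
  y <- rep(seq_len(K), vapply(U, nrow, 1L))
  w <- unlist(lapply(seq_len(K), function(k) cell_w[[k]][idx[[k]]]))

  genv <- list(enc = vector("list", K), dec = vector("list", K))
  dU <- lapply(U, function(u) u * 0)
  dV <- V * 0
  d_enc_mu <- lapply(enc_fwd, function(e) e$mean * 0)
  d_enc_lv <- lapply(enc_fwd, function(e) e$mean * 0)
  losses <- c(disc = 0, data = 0, graph = 0, kl = 0)

  for (k in seq_len(K)) {
    mt <- model$meta[[k]]
    dec <- model$params$dec[[k]]
    sel <- idx[[k]]
    Xb <- ctx$X[[k]][sel, , drop = FALSE]
    if (!is.matrix(Xb)) Xb <- as.matrix(Xb)
    bb <- ctx$batches[[k]][sel]
    nb_cells <- length(sel)
    nv <- length(mt$vidx)
    scale_k <- 1 / (nb_cells * nv)
    Vk <- V[mt$vidx, , drop = FALSE]
    inner <- tcrossprod(U[[k]], Vk)
    alpha <- exp(dec$logalpha)[bb, , drop = FALSE]
    beta <- dec$beta[bb, , drop = FALSE]

    if (mt$family == "NB") {
      tot <- ctx$totals[[k]][sel]
      logits <- inner * alpha + beta
      P <- softmax_rows(logits)
      mu <- P * tot
      # NB log-likelihood inlined with the per-batch-row constants
      # (lgamma/digamma/log of theta) computed once on the B x nv grid
      theta_rows <- exp(dec$logtheta)
      theta <- theta_rows[bb, , drop = FALSE]
      lg_t <- lgamma(theta_rows)[bb, , drop = FALSE]
      dg_t <- digamma(theta_rows)[bb, , drop = FALSE]
      log_t <- dec$logtheta[bb, , drop = FALSE]
      tpm <- theta + mu
      log_tpm <- log(tpm)
      xpt <- Xb + theta
      ll <- sum(lgamma(xpt) - lg_t + Xb * (log(mu) - log_tpm) +
                  theta * (log_t - log_tpm)) - sum(ctx$lgx1[[k]][sel])
      dmu <- scale_k * (Xb / mu - xpt / tpm)
      dP <- dmu * tot
      dlogits <- P * (dP - rowSums(dP * P))
      dtheta_p <- scale_k * (digamma(xpt) - dg_t + log_t + 1 -
                               log_tpm - xpt / tpm) * theta
      glogtheta <- rowsum(dtheta_p, bb)
      gdec <- list(
        logalpha = expand_batch_grad(rowsum(dlogits * inner * alpha, bb),
                                     bb, mt$B),
        beta = expand_batch_grad(rowsum(dlogits, bb), bb, mt$B),
        logtheta = expand_batch_grad(glogtheta, bb, mt$B))
    } else {
      muz <- inner * alpha + beta
      sig <- exp(dec$logsigma)[bb, , drop = FALSE]
      del <- sigmoid(dec$logitdelta)[bb, , drop = FALSE]
      ll <- ziln_log_prob(Xb, muz, sig, del, sum = TRUE)
      gr <- ziln_log_prob_grad(Xb, muz, sig, del)
      dlogits <- scale_k * gr$dmu
      gdec <- list(
        logalpha = expand_batch_grad(rowsum(dlogits * inner * alpha, bb),
                                     bb, mt$B),
        beta = expand_batch_grad(rowsum(dlogits, bb), bb, mt$B),
        logsigma = expand_batch_grad(
          rowsum(scale_k * gr$dsigma * sig, bb), bb, mt$B),
        logitdelta = expand_batch_grad(
          rowsum(scale_k * gr$ddelta * del * (1 - del), bb), bb, mt$B))
    }
    losses["data"] <- losses["data"] + ll * scale_k
    if (want_grads) {
      dU[[k]] <- dU[[k]] + (dlogits * alpha) %*% Vk
      dV[mt$vidx, ] <- dV[mt$vidx, ] + crossprod(dlogits * alpha, U[[k]])
      genv$dec[[k]] <- gdec
    }

    klu <- kl_diag_normal(enc_fwd[[k]]$mean, enc_fwd[[k]]$logvar)
    losses["kl"] <- losses["kl"] + sum(klu) * scale_k * cfg$lam_kl
    if (want_grads) {
      kg <- kl_diag_normal_grad(enc_fwd[[k]]$mean, enc_fwd[[k]]$logvar)
      d_enc_mu[[k]] <- d_enc_mu[[k]] - cfg$lam_kl * scale_k * kg$dmean
      d_enc_lv[[k]] <- d_enc_lv[[k]] - cfg$lam_kl * scale_k * kg$dlogvar
    }
  }

  # graph term
  gll <- graph_ll_core(model, V, mb, grad = want_grads)
  nvtx <- length(model$vertices)
  klV <- kl_diag_normal(gf$mean, gf$logvar)
  losses["graph"] <- cfg$lam_g * K * (gll$ll - cfg$lam_kl * sum(klV) / nvtx)

  # adversarial term through the (frozen) discriminator
  d2 <- disc_forward(model, Uall + noise2)
  g2 <- disc_ce_grad(d2$prob, y, w, K)
  losses["disc"] <- g2$loss
  J <- cfg$lam_d * g2$loss + losses["data"] - losses["kl"] +
    losses["graph"]

  if (!want_grads)
    return(list(J = unname(J), losses = losses, grads = NULL, U = U))

  dV <- dV + cfg$lam_g * K * gll$dV
  kgV <- kl_diag_normal_grad(gf$mean, gf$logvar)
  dgmu <- -cfg$lam_g * K * cfg$lam_kl / nvtx * kgV$dmean
  dglv <- -cfg$lam_g * K * cfg$lam_kl / nvtx * kgV$dlogvar

  db2 <- disc_backward(model, d2, cfg$lam_d * g2$dlogits)
  off <- 0
  for (k in seq_len(K)) {
    nk <- nrow(U[[k]])
    dU[[k]] <- dU[[k]] + db2$dU[off + seq_len(nk), , drop = FALSE]
    off <- off + nk
  }

  # backprop through the reparameterisation into the encoders / GCN
  for (k in seq_len(K)) {
    dmu <- d_enc_mu[[k]] + dU[[k]]
    dlv <- d_enc_lv[[k]] +
      dU[[k]] * 0.5 * exp(enc_fwd[[k]]$logvar / 2) * eps_u[[k]]
    genv$enc[[k]] <- encoder_backward(model, k, enc_fwd[[k]], dmu, dlv)
  }
  dgmu <- dgmu + dV
  dglv <- dglv + dV * 0.5 * exp(gf$logvar / 2) * epsV
  genv$gcn <- graph_encoder_backward(model, gf, dgmu, dglv)

  list(J = unname(J), losses = losses, grads = genv, U = U)
}

# One full adversarial iteration on prepared minibatches: step 1 updates
# the discriminator by weighted cross entropy on noise-perturbed
# embeddings; step 2 ascends the generator objective.
glue_iteration <- function(model, ctx, idx, tau, cell_w, states, lr) {
  cfg <- model$config
  K <- ctx$K
  m <- cfg$m

  # reparameterisation draws shared by both steps
  enc_fwd <- list(); U <- list(); eps_u <- list()
  for (k in seq_len(K)) {
    ef <- encoder_forward(model, k, ctx$Xred[[k]][idx[[k]], , drop = FALSE])
    eps <- matrix(rnorm(length(ef$mean)), nrow(ef$mean))
    U[[k]] <- ef$mean + exp(ef$logvar / 2) * eps
    enc_fwd[[k]] <- ef; eps_u[[k]] <- eps
  }
  gf <- graph_encoder_forward(model)
  epsV <- matrix(rnorm(length(gf$mean)), nrow(gf$mean))

  Uall <- do.call(rbind, U)
  y <- rep(seq_len(K), vapply(U, nrow, 1L))
  w <- unlist(lapply(seq_len(K), function(k) cell_w[[k]][idx[[k]]]))

  # additive discriminator noise ~ N(0, tau * factor * minibatch variance)
  noise_sd <- if (tau > 0) {
    n_all <- nrow(Uall)
    v <- (colMeans(Uall^2) - colMeans(Uall)^2) * n_all / (n_all - 1)
    sqrt(tau * cfg$noise_factor * pmax(v, 1e-12))
  } else rep(0, m)
  draw_noise <- function() {
    if (all(noise_sd == 0)) return(matrix(0, nrow(Uall), m))
    matrix(rnorm(nrow(Uall) * m), ncol = m) %*% diag(noise_sd, m)
  }

  # --- step 1: discriminator update (embeddings detached) ---
  d1 <- disc_forward(model, Uall + draw_noise())
  g1 <- disc_ce_grad(d1$prob, y, w, K)
  db1 <- disc_backward(model, d1, cfg$lam_d * g1$dlogits)
  up <- rmsprop_update(model$params$disc, db1$grads, states$disc, lr)
  model$params$disc <- up$params; states$disc <- up$state

  # --- step 2: generator update ---
  n_eb <- cfg$edge_batch %||% sum(vapply(U, nrow, 1L))
  mb <- sample_graph_minibatch(model, min(n_eb, 4 * length(model$edges$i)),
                               cfg$n_neg)
  fb <- gen_forward_backward(model, ctx, idx, cell_w, eps_u, epsV, mb,
                             draw_noise(), enc_cache = enc_fwd,
                             gf_cache = gf)
  gen_params <- list(enc = model$params$enc, dec = model$params$dec,
                     gcn = model$params$gcn)
  up <- rmsprop_update(gen_params, fb$grads, states$gen, lr,
                       direction = -1)
  model$params$enc <- up$params$enc
  model$params$dec <- up$params$dec
  model$params$gcn <- up$params$gcn
  states$gen <- up$state

  if (!all(is.finite(unlist(fb$losses))))
    stop("glue_iteration: non-finite loss (disc=", fb$losses["disc"],
         ", data=", fb$losses["data"], ", graph=", fb$losses["graph"], ")")
  list(model = model, states = states, losses = fb$losses)
}

# Scatter per-present-batch gradient rows into the full B x features grid.
expand_batch_grad <- function(g_present, bb, B) {
  out <- matrix(0, B, ncol(g_present))
  out[as.integer(rownames(g_present)), ] <- g_present
  out
}

#' One adversarial training iteration
#'
#' Runs a single two-step stochastic gradient iteration: the
#' discriminator is updated on the current (noise-perturbed) cell
#' embeddings, then the data and graph autoencoders are updated to
#' maximise the adversarial, graph and data objectives jointly. Exposed
#' mainly for inspection; [fit_glue()] drives the full schedule.
#'
#' @param model A [glue_model()] (with its layers attached).
#' @param layers List of the model's [omics_layer()] objects.
#' @param indices Optional list of per-layer cell indices for the
#'   minibatch (default: a random minibatch per layer).
#' @param tau Noise temperature in \[0, 1\].
#' @param weights Optional per-layer list of balancing weights.
#' @param seed Seed for minibatch and reparameterisation draws.
#' @return List with the updated `model` and the iteration's `losses`.
#' @export
train_step <- function(model, layers, indices = NULL, tau = 1,
                       weights = NULL, seed = 1) {
  ctx <- build_train_ctx(model, layers)
  cfg <- model$config
  with_seed(seed, {
    if (is.null(indices))
      indices <- lapply(ctx$N, function(n)
        sample.int(n, min(cfg$minibatch, n)))
    if (is.null(weights))
      weights <- lapply(ctx$N, function(n) rep(1, n))
    states <- list(disc = tree_zeros(model$params$disc),
                   gen = tree_zeros(list(enc = model$params$enc,
                                         dec = model$params$dec,
                                         gcn = model$params$gcn)))
    st <- glue_iteration(model, ctx, indices, tau, weights, states, cfg$lr)
    list(model = st$model, losses = st$losses)
  })
}

# ---- balancing weights ---------------------------------------------------

#' Cell-specific balancing weights from a coarse alignment
#'
#' Leiden-clusters each layer's coarse embeddings separately (on a
#' cosine k-NN graph), then weights each cluster by the summed
#' fourth-power cosine similarity to its matching clusters (centroid
#' cosine > 0.5) in the other layers, divided by the cluster size. Every
#' cell inherits its cluster's weight; clusters with no cross-layer
#' match receive a small positive floor so per-layer normalisers stay
#' positive.
#'
#' @param embeddings List of per-layer embedding matrices (cells x m).
#' @param resolution Leiden resolution parameter.
#' @param knn Neighbours in the per-layer cosine k-NN graph.
#' @param weight_floor Weight for unmatched clusters.
#' @param seed Integer seed (Leiden refinement is stochastic).
#' @return List with `weights` (per-layer numeric vectors) and
#'   `clusters` (per-layer integer assignments).
#' @export
estimate_balancing_weights <- function(embeddings, resolution = 1,
                                       knn = 15, weight_floor = 1e-4,
                                       seed = 1) {
  K <- length(embeddings)
  clus <- list()
  with_seed(seed, {
    for (k in seq_len(K)) {
      E <- l2_normalize_rows(embeddings[[k]])
      n <- nrow(E)
      kk <- min(knn, n - 1)
      sim <- tcrossprod(E)
      diag(sim) <- -Inf
      edges <- NULL
      nn <- t(apply(sim, 1, function(s) order(s, decreasing = TRUE)[seq_len(kk)]))
      ei <- rep(seq_len(n), kk); ej <- as.vector(nn)
      g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
      g <- igraph::simplify(g)
      cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution)
      clus[[k]] <- igraph::membership(cl)
      if (length(unique(clus[[k]])) < 1)
        stop("estimate_balancing_weights: layer produced zero clusters")
    }
  })
  cw <- compute_cluster_weights(embeddings, clus, weight_floor)
  weights <- lapply(seq_len(K), function(k) cw[[k]][clus[[k]]])
  list(weights = weights, clusters = clus)
}

# Direct evaluation of the cluster-weight formula given embeddings and
# cluster assignments (shared by the estimator and its tests).
compute_cluster_weights <- function(embeddings, clusters, weight_floor = 1e-4,
                                    cos_threshold = 0.5, power = 4) {
  K <- length(embeddings)
  cents <- list(); sizes <- list()
  for (k in seq_len(K)) {
    cl <- clusters[[k]]
    ids <- sort(unique(cl))
    cents[[k]] <- t(vapply(ids, function(i)
      colMeans(embeddings[[k]][cl == i, , drop = FALSE]),
      numeric(ncol(embeddings[[k]]))))
    sizes[[k]] <- vapply(ids, function(i) sum(cl == i), 1)
  }
  out <- list()
  for (k in seq_len(K)) {
    nk <- nrow(cents[[k]])
    w <- numeric(nk)
    for (i in seq_len(nk)) {
      f_sum <- 0
      for (k2 in seq_len(K)) {
        if (k2 == k) next
        cs <- as.vector(cents[[k2]] %*% cents[[k]][i, ]) /
          (sqrt(rowSums(cents[[k2]]^2)) * sqrt(sum(cents[[k]][i, ]^2)))
        f_sum <- f_sum + sum(cs[cs > cos_threshold]^power)
      }
      w[i] <- f_sum / sizes[[k]][i]
    }
    w[w <= 0] <- weight_floor
    out[[k]] <- w
  }
  out
}

# ---- the two-stage fitting procedure ------------------------------------

#' Fit the graph-guided integration model
#'
#' Two-stage adversarial training. Stage 1 pretrains with uniform
#' balancing weights and full discriminator noise (temperature tau = 1),
#' producing a coarse alignment that is robust to composition imbalance.
#' Balancing weights are then estimated from the coarse embeddings with
#' [estimate_balancing_weights()], and stage 2 fine-tunes with those
#' weights while the noise anneals linearly to zero. A 10% validation
#' split drives learning-rate reduction (divide by 10 on plateau) and
#' early stopping; all schedule budgets are iteration-equivalents at
#' learning rate 0.002 (see [glue_config()]).
#'
#' @param layers List of [omics_layer()] objects (2 or more for
#'   adversarial alignment).
#' @param graph A [guidance_graph()] covering all layers' features.
#' @param config A [glue_config()].
#' @param reduction Per-layer front-end choice, see [glue_model()].
#' @param verbose Print per-epoch progress.
#' @return A fitted `"glue_model"` with `history` (per-epoch data.frame:
#'   stage, epoch, tau, lr, losses, validation loss, best validation
#'   loss) and `balancing_weights`.
#' @export
fit_glue <- function(layers, graph, config = glue_config(),
                     reduction = NULL, verbose = FALSE) {
  model <- glue_model(layers, graph, config, reduction)
  layers <- attr(model, "layers")
  cfg <- config
  ctx <- build_train_ctx(model, layers)
  K <- ctx$K

  with_seed(cfg$seed, {
    # validation split
    val_idx <- lapply(ctx$N, function(n)
      sort(sample.int(n, max(1, floor(cfg$val_frac * n)))))
    train_idx <- lapply(seq_len(K), function(k)
      setdiff(seq_len(ctx$N[k]), val_idx[[k]]))
    n_train <- vapply(train_idx, length, 1L)
    mb_size <- pmin(cfg$minibatch, n_train)
    ipe <- max(ceiling(n_train / mb_size))
    iters_to_epochs <- function(iters)
      max(1L, ceiling(iters * (0.002 / cfg$lr) / ipe))
    ep_anneal <- iters_to_epochs(cfg$anneal_iters)
    ep_pat_lr <- iters_to_epochs(cfg$patience_lr_iters)
    ep_pat_stop <- iters_to_epochs(cfg$patience_stop_iters)
    ep_max <- iters_to_epochs(cfg$max_iters)

    # fixed deterministic graph minibatch for validation
    val_mb <- sample_graph_minibatch(model, length(model$edges$i),
                                     cfg$n_neg)

    states <- list(disc = tree_zeros(model$params$disc),
                   gen = tree_zeros(list(enc = model$params$enc,
                                         dec = model$params$dec,
                                         gcn = model$params$gcn)))
    history <- list()
    uniform_w <- lapply(ctx$N, function(n) rep(1, n))

    val_loss_fn <- function(model) {
      gf <- graph_encoder_forward(model)
      V <- gf$mean
      total <- cfg$lam_g * K *
        (sum(kl_diag_normal(gf$mean, gf$logvar)) / length(model$vertices) -
           graph_ll_core(model, V, val_mb)$ll)
      # adversarial term (generator view): a discriminator that still
      # separates the layers keeps the validation loss high, so early
      # stopping cannot fire before the layers are mixed
      val_means <- lapply(seq_len(K), function(k)
        encoder_forward(model, k,
                        ctx$Xred[[k]][val_idx[[k]], , drop = FALSE])$mean)
      ld <- 0
      for (k in seq_len(K)) {
        p <- disc_forward(model, val_means[[k]])$prob
        ld <- ld - mean(log(pmax(p[, k], 1e-300))) / K
      }
      total <- total - cfg$lam_d * ld
      for (k in seq_len(K)) {
        mt <- model$meta[[k]]
        sel <- val_idx[[k]]
        ef <- encoder_forward(model, k,
                              ctx$Xred[[k]][sel, , drop = FALSE])
        u <- ef$mean
        Xb <- as.matrix(ctx$X[[k]][sel, , drop = FALSE])
        bb <- ctx$batches[[k]][sel]
        dec <- model$params$dec[[k]]
        Vk <- V[mt$vidx, , drop = FALSE]
        ll <- if (mt$family == "NB") {
          mu <- nb_decode(u, Vk, dec, bb, ctx$totals[[k]][sel])
          if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
          nb_log_prob(Xb, mu, exp(dec$logtheta)[bb, , drop = FALSE])
        } else {
          muz <- ziln_decode(u, Vk, dec, bb)
          if (is.null(dim(muz))) muz <- matrix(muz, nrow = 1)
          ziln_log_prob(Xb, muz, exp(dec$logsigma)[bb, , drop = FALSE],
                        sigmoid(dec$logitdelta)[bb, , drop = FALSE])
        }
        kl <- sum(kl_diag_normal(ef$mean, ef$logvar))
        total <- total + (-ll + cfg$lam_kl * kl) /
          (length(sel) * length(mt$vidx))
      }
      total
    }

    run_epoch <- function(model, states, tau, cell_w, lr) {
      perm <- lapply(train_idx, sample)
      acc <- c(disc = 0, data = 0, graph = 0, kl = 0)
      for (it in seq_len(ipe)) {
        idx <- lapply(seq_len(K), function(k) {
          pos <- ((it - 1) * mb_size[k] + seq_len(mb_size[k]) - 1) %%
            n_train[k] + 1
          perm[[k]][pos]
        })
        st <- glue_iteration(model, ctx, idx, tau, cell_w, states, lr)
        model <- st$model; states <- st$states
        acc <- acc + st$losses
      }
      list(model = model, states = states, losses = acc / ipe)
    }

    run_stage <- function(model, states, stage, epochs, cell_w,
                          tau_fn, early_stop, restore_best = TRUE) {
      lr <- cfg$lr
      best_val <- Inf; best_params <- model$params
      wait_lr <- 0; wait_stop <- 0; bad_val <- 0
      for (ep in seq_len(epochs)) {
        tau <- tau_fn(ep)
        r <- run_epoch(model, states, tau, cell_w, lr)
        model <- r$model; states <- r$states
        vl <- val_loss_fn(model)
        if (!is.finite(vl)) {
          bad_val <- bad_val + 1
          if (bad_val >= 2) {
            warning("fit_glue: validation loss diverged; ",
                    "returning best checkpoint")
            model$params <- best_params
            break
          }
        } else bad_val <- 0
        improved <- is.finite(vl) && vl < best_val - 1e-6
        if (improved) {
          best_val <- vl; best_params <- model$params
          wait_lr <- 0; wait_stop <- 0
        } else {
          wait_lr <- wait_lr + 1; wait_stop <- wait_stop + 1
        }
        history[[length(history) + 1]] <<- data.frame(
          stage = stage, epoch = ep, tau = tau, lr = lr,
          loss_disc = r$losses["disc"], loss_data = r$losses["data"],
          loss_graph = r$losses["graph"], loss_kl = r$losses["kl"],
          val_loss = vl, best_val_loss = min(best_val, vl))
        if (verbose)
          message(sprintf(
            "[stage %d] epoch %d tau=%.2f lr=%.2e val=%.4f best=%.4f",
            stage, ep, tau, lr, vl, best_val))
        if (early_stop) {
          if (wait_lr >= ep_pat_lr) { lr <- lr / 10; wait_lr <- 0 }
          if (wait_stop >= ep_pat_stop) break
        }
      }
      if (restore_best) model$params <- best_params
      list(model = model, states = states)
    }

    # stage 1: uniform weights, full noise, pretrained to plateau
    s1 <- run_stage(model, states, 1L, ep_max, uniform_w,
                    function(ep) 1, early_stop = TRUE)
    model <- s1$model; states <- s1$states

    # balancing weights from the coarse alignment
    emb <- lapply(seq_len(K), function(k)
      encoder_forward(model, k, ctx$Xred[[k]])$mean)
    bw <- estimate_balancing_weights(emb, cfg$leiden_resolution,
                                     cfg$knn_balance, cfg$weight_floor,
                                     seed = child_seed(cfg$seed, 77))
    model$balancing_weights <- bw$weights

    # stage 2: balanced weights, noise annealing linearly to zero; the
    # plateau rules only engage in the final (noise-free) phase, so the
    # annealing itself is never cut short
    tau_fn <- function(ep) max(0, 1 - ep / ep_anneal)
    s2 <- run_stage(model, states, 2L, ep_anneal, bw$weights, tau_fn,
                    early_stop = FALSE, restore_best = FALSE)
    model <- s2$model; states <- s2$states

    # final stage: noise-free fine-tuning with lr reduction and early
    # stopping on the validation plateau
    s3 <- run_stage(model, states, 3L, ep_max, bw$weights,
                    function(ep) 0, early_stop = TRUE)
    model <- s3$model

    model$fitted <- TRUE
    model$history <- do.call(rbind, history)
    rownames(model$history) <- NULL
    attr(model, "layers") <- layers
    model
  })
}

# ---- metacell aggregation ------------------------------------------------

#' Aggregate cells into metacells by k-means in the reduced space
#'
#' Clusters a layer's cells with k-means on its reduced coordinates,
#' sums counts (NB layers) or averages levels (ZILN layers) per cluster,
#' and averages the reduced coordinates. Used to combat sparsity and to
#' pretrain on large datasets.
#'
#' @param layer An [omics_layer()] with a fitted reduction (see
#'   [reduce_layer()]).
#' @param k Number of metacells (must be < number of cells, or equal for
#'   identity aggregation).
#' @param seed Integer seed for the k-means initialisation.
#' @return List with `layer` (the aggregated [omics_layer()], reduction
#'   carried over) and `assignment` (metacell index per original cell).
#' @export
aggregate_metacells <- function(layer, k, seed = 1) {
  if (is.null(layer$reduced))
    stop("aggregate_metacells: layer has no fitted reduction")
  n <- nrow(layer$X)
  if (k > n) stop("aggregate_metacells: k must not exceed the cell count")
  with_seed(seed, {
    a <- if (k == n) seq_len(n)
      else kmeans(layer$reduced, centers = k, nstart = 1,
                  iter.max = 50)$cluster
    used <- sort(unique(a))
    if (length(used) < k)
      warning("aggregate_metacells: ", k - length(used),
              " empty cluster(s) dropped")
    a <- match(a, used)
    Xm <- rowsum(as.matrix(layer$X), a)
    if (layer$family == "ZILN") Xm <- Xm / as.vector(table(a))
    red <- rowsum(layer$reduced, a) / as.vector(table(a))
    bt <- vapply(split(layer$batches, a), function(b)
      as.integer(names(which.max(table(b)))), 1L)
    agg <- omics_layer(Xm, features = layer$features, family = layer$family,
                       name = paste0(layer$name, "_meta"), batches = bt)
    agg$reduced <- red
    agg$reduction <- layer$reduction
    list(layer = agg, assignment = a)
  })
}
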