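#' Model and training configuration
#'
#' Collects every tunable of the integration model and its two-stage
#' adversarial training procedure. Budgets expressed in
#' "iteration-equivalents" are converted to epochs at run time as
#' `ceiling(budget * (0.002 / lr) / iterations_per_epoch)`, so the
#' effective learning progress is independent of data size and learning
#' rate.
#'
#' @param m Shared embedding dimension of cells and features.
#' @param hidden Hidden width of the data-encoder MLPs (2 hidden layers).
#' @param hidden_disc Hidden width of the discriminator MLP.
#' @param hidden_graph Hidden width of the graph-convolutional encoder.
#' @param r_reduce Dimensionality of the fixed PCA/LSI encoder front-end.
#' @param lam_d Weight of the adversarial alignment term.
#' @param lam_g Weight of the graph ELBO term (multiplied by the number
#'   of layers in the objective).
#' @param lam_kl Scale on the cell-embedding KL term.
#' @param lr RMSprop learning rate.
#' @param minibatch Cells drawn per layer per iteration.
#' @param noise_factor Additive discriminator noise covariance is this
#'   factor times the per-minibatch empirical embedding variance.
#' @param anneal_iters,patience_lr_iters,patience_stop_iters,max_iters
#'   Iteration-equivalent budgets (at lr 0.002) for noise annealing,
#'   learning-rate reduction patience, early stopping patience, and the
#'   hard epoch cap.
#' @param val_frac Fraction of cells held out as a validation set.
#' @param n_neg Negative samples per sampled guidance edge.
#' @param neg_dist Negative-sampling distribution over vertices:
#'   `"uniform"` or `"degree"` (proportional to degree^0.75).
#' @param edge_batch Guidance edges sampled per iteration (default: the
#'   number of data cells in the iteration's minibatches).
#' @param leiden_resolution,knn_balance Leiden resolution and k-NN graph
#'   size used when estimating balancing weights.
#' @param weight_floor Balancing weight assigned to clusters with no
#'   cross-layer match (keeps the per-layer normaliser positive).
#' @param seed Integer seed governing initialisation, minibatching and
#'   all sampling.
#' @return A list of class `"glue_config"`.
#' @export
glue_config <- function(m = 50, hidden = 256, hidden_disc = 256,
                        hidden_graph = 256, r_reduce = 100,
                        lam_d = 0.05, lam_g = 0.02, lam_kl = 1,
                        lr = 0.002, minibatch = 128, noise_factor = 1.5,
                        anneal_iters = 4000, patience_lr_iters = 1000,
                        patience_stop_iters = 2000, max_iters = 16000,
                        val_frac = 0.1, n_neg = 1,
                        neg_dist = c("uniform", "degree"),
                        edge_batch = NULL, leiden_resolution = 1,
                        knn_balance = 15, weight_floor = 1e-4, seed = 0) {
  neg_dist <- match.arg(neg_dist)
  cfg <- as.list(environment())
  stopifnot(m >= 2, lr > 0, val_frac > 0, val_frac < 1, n_neg >= 1,
            anneal_iters > 0, max_iters > 0)
  class(cfg) <- "glue_config"
  cfg
}

# ---- model construction --------------------------------------------------

init_glue_params <- function(meta, n_vertices, cfg) {
  K <- length(meta)
  enc <- vector("list", K); dec <- vector("list", K)
  for (k in seq_len(K)) {
    enc[[k]] <- list(core = mlp_init(meta[[k]]$r, cfg$hidden, depth = 2),
                     mu = head_init(cfg$hidden, cfg$m),
                     lv = head_init(cfg$hidden, cfg$m))
    nv <- length(meta[[k]]$features); B <- meta[[k]]$B
    dec[[k]] <- if (meta[[k]]$family == "NB") {
      list(logalpha = matrix(0, B, nv), beta = matrix(0, B, nv),
           logtheta = matrix(0, B, nv))
    } else {
      list(logalpha = matrix(0, B, nv), beta = matrix(0, B, nv),
           logsigma = matrix(0, B, nv), logitdelta = matrix(0, B, nv))
    }
  }
  gcn <- list(W1 = init_mat(n_vertices, cfg$hidden_graph,
                            scale = sqrt(1 / cfg$m)),
              mu = head_init(cfg$hidden_graph, cfg$m),
              lv = head_init(cfg$hidden_graph, cfg$m))
  disc <- list(core = mlp_init(cfg$m, cfg$hidden_disc, depth = 2),
               out = head_init(cfg$hidden_disc, K))
  list(enc = enc, dec = dec, gcn = gcn, disc = disc)
}

#' Build an untrained integration model
#'
#' Assembles the parameter bundle: one variational encoder/decoder pair
#' per omics layer (negative binomial or zero-inflated log-normal, with
#' batch-specific decoder parameters), a graph-convolutional variational
#' encoder over the guidance graph, and an omics-layer discriminator.
#' Layers are reduced with [reduce_layer()] first if they are not
#' already.
#'
#' @param layers List of [omics_layer()] objects (named, or names taken
#'   from the layers).
#' @param graph A [guidance_graph()] whose vertices cover every layer's
#'   features.
#' @param config A [glue_config()].
#' @param reduction Optional character vector (recycled or named by
#'   layer) choosing the front-end per layer: `"pca"` or `"lsi"`.
#'   Defaults to LSI for layers whose name matches accessibility
#'   conventions (`atac`/`peak`/`access`) and PCA otherwise.
#' @return An object of class `"glue_model"` (untrained; see
#'   [fit_glue()]).
#' @export
glue_model <- function(layers, graph, config = glue_config(),
                       reduction = NULL) {
  stopifnot(inherits(graph, "guidance_graph"), length(layers) >= 1)
  nm <- vapply(layers, function(l) l$name, "")
  if (is.null(names(layers))) names(layers) <- nm
  validate_graph(graph)
  vids <- graph$vertices$id
  vmap <- stats::setNames(seq_along(vids), vids)
  with_seed(config$seed, {
    meta <- list()
    for (k in seq_along(layers)) {
      ly <- layers[[k]]
      missing <- setdiff(ly$features, vids)
      if (length(missing))
        stop("glue_model: layer '", ly$name, "' has features absent from ",
             "the guidance graph: ", paste(head(missing, 5), collapse = ", "))
      if (is.null(ly$reduced)) {
        meth <- if (!is.null(reduction)) {
          if (!is.null(names(reduction))) reduction[[ly$name]]
          else rep_len(reduction, length(layers))[k]
        } else if (grepl("atac|peak|access", ly$name, ignore.case = TRUE))
          "lsi" else "pca"
        ly <- reduce_layer(ly, r = config$r_reduce, method = meth)
        layers[[k]] <- ly
      }
      red_center <- colMeans(ly$reduced)
      red_scale <- apply(ly$reduced, 2, sd)
      red_scale[red_scale == 0] <- 1
      meta[[k]] <- list(name = ly$name, family = ly$family,
                        features = ly$features,
                        vidx = unname(vmap[ly$features]),
                        B = max(ly$batches), r = ncol(ly$reduced),
                        red_center = red_center, red_scale = red_scale)
    }
    names(meta) <- names(layers)
    edges <- collapse_graph(graph)
    e_ii <- unname(vmap[edges$i]); e_jj <- unname(vmap[edges$j])
    adj <- vector("list", length(vids))
    for (t in seq_along(e_ii)) {
      adj[[e_ii[t]]] <- c(adj[[e_ii[t]]], e_jj[t])
      adj[[e_jj[t]]] <- c(adj[[e_jj[t]]], e_ii[t])
    }
    adj <- lapply(adj, unique)
    deg <- pmax(1, lengths(adj) - 1) # degree excluding self-loop
    adj_pattern <- Matrix::sparseMatrix(
      i = c(e_ii, e_jj), j = c(e_jj, e_ii), x = TRUE,
      dims = c(length(vids), length(vids)), use.last.ij = TRUE)
    model <- structure(list(
      config = config,
      layer_names = names(meta),
      meta = meta,
      vertices = vids,
      A = graph_adjacency(graph),
      edges = list(i = e_ii, j = e_jj, sign = edges$sign,
                   weight = edges$weight, adj = adj,
                   neg_prob = if (config$neg_dist == "degree")
                     deg^0.75 / sum(deg^0.75) else NULL),
      adj_pattern = adj_pattern,
      graph_fingerprint = graph_fingerprint(graph),
      params = init_glue_params(meta, length(vids), config),
      fitted = FALSE, history = NULL, balancing_weights = NULL
    ), class = "glue_model")
    attr(model, "layers") <- layers
    model
  })
}

# Order-independent numeric fingerprint of a graph's edge multiset, used
# to refuse embedding extraction against a different graph.
graph_fingerprint <- function(g) {
  e <- g$edges
  key <- sort(paste(pmin(e$i, e$j), pmax(e$i, e$j), e$sign,
                    signif(e$weight, 9), e$tag, sep = "|"))
  h <- 0
  for (s in key) h <- (h * 31 + sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))) %% 2147483647
  h
}

# ---- forward passes ------------------------------------------------------

clamp_lv <- function(lv, lim = 10) pmin(pmax(lv, -lim), lim)
clamp_lv_grad <- function(lv, lim = 10) (lv > -lim & lv < lim) * 1

# Cell encoder: standardised reduced coordinates -> diagonal-normal
# posterior over u. Returns mean, logvar and the forward cache.
encoder_forward <- function(model, k, Xred) {
  mt <- model$meta[[k]]
  Z <- sweep(sweep(Xred, 2, mt$red_center), 2, mt$red_scale, `/`)
  pe <- model$params$enc[[k]]
  fw <- mlp_forward(pe$core, Z)
  mu <- head_forward(pe$mu, fw$H)
  lv_raw <- head_forward(pe$lv, fw$H)
  list(mean = mu, logvar = clamp_lv(lv_raw), lv_raw = lv_raw,
       H = fw$H, cache = fw$cache)
}

encoder_backward <- function(model, k, fwd, dmu, dlv) {
  pe <- model$params$enc[[k]]
  dlv <- dlv * clamp_lv_grad(fwd$lv_raw)
  hb_mu <- head_backward(pe$mu, fwd$H, dmu)
  hb_lv <- head_backward(pe$lv, fwd$H, dlv)
  cb <- mlp_backward(pe$core, fwd$cache, hb_mu$dH + hb_lv$dH)
  list(core = list(W = cb$W, b = cb$b),
       mu = list(W = hb_mu$W, b = hb_mu$b),
       lv = list(W = hb_lv$W, b = hb_lv$b))
}

# Graph encoder: one signed-normalised graph convolution with a
# leaky-rectifier, then plain linear mean / log-variance heads (a
# single propagation hop; deeper smoothing would blur data-driven
# differences between a vertex and its prior neighbours).
graph_encoder_forward <- function(model) {
  pg <- model$params$gcn
  A <- model$A
  H1pre <- as.matrix(A %*% pg$W1)
  H1 <- lrelu(H1pre, LRELU_SLOPE)
  mu <- head_forward(pg$mu, H1)
  lv_raw <- head_forward(pg$lv, H1)
  list(mean = mu, logvar = clamp_lv(lv_raw), lv_raw = lv_raw,
       H1pre = H1pre, H1 = H1)
}

graph_encoder_backward <- function(model, fwd, dmu, dlv) {
  pg <- model$params$gcn
  A <- model$A
  dlv <- dlv * clamp_lv_grad(fwd$lv_raw)
  hb_mu <- head_backward(pg$mu, fwd$H1, dmu)
  hb_lv <- head_backward(pg$lv, fwd$H1, dlv)
  dH1 <- hb_mu$dH + hb_lv$dH
  dH1pre <- dH1 * lrelu_grad(fwd$H1pre, LRELU_SLOPE)
  dW1 <- as.matrix(A %*% dH1pre) # A is symmetric
  list(W1 = dW1,
       mu = list(W = hb_mu$W, b = hb_mu$b),
       lv = list(W = hb_lv$W, b = hb_lv$b))
}

#' Negative binomial decoder mean
#'
#' Maps a cell embedding and the layer's feature embeddings to the NB
#' mean vector: softmax of the batch-scaled inner products times the
#' cell's total count, so the reconstructed library size matches the
#' observed one exactly.
#'
#' @param u Cell embedding vector (length m) or N x m matrix.
#' @param V_k Feature embeddings for the layer (features x m).
#' @param theta_k Decoder parameter list with `logalpha` and `beta`
#'   (B x features).
#' @param batch Batch index (scalar or per-cell vector).
#' @param total Positive per-cell total count(s).
#' @return Mean matrix/vector with rows summing to `total`.
#' @export
nb_decode <- function(u, V_k, theta_k, batch = 1, total) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (any(total <= 0)) stop("nb_decode: total count must be positive")
  batch <- rep_len(batch, nrow(u))
  alpha <- exp(theta_k$logalpha)[batch, , drop = FALSE]
  beta <- theta_k$beta[batch, , drop = FALSE]
  logits <- tcrossprod(u, V_k) * alpha + beta
  p <- softmax_rows(logits)
  drop(p * total)
}

#' Zero-inflated log-normal decoder mean
#'
#' Affine map of the cell-feature inner products to the log-scale mean:
#' `mu = alpha * (V_k u) + beta`, with batch-specific `alpha`, `beta`.
#'
#' @inheritParams nb_decode
#' @return Log-scale mean matrix/vector.
#' @export
ziln_decode <- function(u, V_k, theta_k, batch = 1) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  batch <- rep_len(batch, nrow(u))
  alpha <- exp(theta_k$logalpha)[batch, , drop = FALSE]
  beta <- theta_k$beta[batch, , drop = FALSE]
  drop(tcrossprod(u, V_k) * alpha + beta)
}

# Discriminator forward: cell embeddings -> per-layer class probabilities.
disc_forward <- function(model, U) {
  pd <- model$params$disc
  fw <- mlp_forward(pd$core, U)
  logits <- head_forward(pd$out, fw$H)
  list(prob = softmax_rows(logits), H = fw$H, cache = fw$cache)
}

disc_backward <- function(model, fwd, dlogits) {
  pd <- model$params$disc
  hb <- head_backward(pd$out, fwd$H, dlogits)
  cb <- mlp_backward(pd$core, fwd$cache, hb$dH)
  list(grads = list(core = list(W = cb$W, b = cb$b),
                    out = list(W = hb$W, b = hb$b)),
       dU = cb$dX)
}

#' Discriminator probabilities for cell embeddings
#'
#' Softmax probabilities (one per omics layer) that each embedding came
#' from each layer, from the model's adversarial discriminator.
#'
#' @param model A [glue_model()].
#' @param u Embedding vector or N x m matrix.
#' @return Probability vector/matrix with rows summing to 1.
#' @export
discriminate <- function(model, u) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  drop(disc_forward(model, u)$prob)
}

# ---- graph likelihood ----------------------------------------------------

# numerically stable, branch-free log of the sigmoid
log_sigmoid <- function(a) pmin(a, 0) - log1p(exp(-abs(a)))

# Sample guidance edges proportionally to weight and negatives from the
# non-neighbourhood; returns index vectors reused by forward + backward.
# Negative draws are vectorised with rejection of adjacent candidates
# (fast on the sparse graphs this model consumes).
sample_graph_minibatch <- function(model, n_edges, n_neg) {
  ed <- model$edges
  ne <- length(ed$i)
  es <- sample.int(ne, n_edges, replace = TRUE, prob = ed$weight)
  nv <- length(model$vertices)
  full <- lengths(ed$adj) >= nv # vertices adjacent to everything
  if (any(full[ed$i[es]]))
    warning("graph sampling: vertex adjacent to all others; ",
            "excluding only self for its negatives")
  ii <- rep(ed$i[es], n_neg)
  n_tot <- length(ii)
  cand <- integer(n_tot)
  todo <- seq_len(n_tot)
  adjmat <- model$adj_pattern
  for (round in 1:50) {
    draw <- if (is.null(ed$neg_prob)) sample.int(nv, length(todo),
                                                 replace = TRUE)
    else sample.int(nv, length(todo), replace = TRUE, prob = ed$neg_prob)
    cand[todo] <- draw
    it <- ii[todo]
    bad <- if (is.null(adjmat)) {
      mapply(function(i, j) j %in% ed$adj[[i]], it, draw)
    } else adjmat[cbind(it, draw)]
    bad <- bad & !(full[it] & draw != it) # full vertices: only self barred
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo)) # pathological density: fall back per element
    for (t in todo) {
      excl <- if (full[ii[t]]) ii[t] else ed$adj[[ii[t]]]
      cand[t] <- sample(setdiff(seq_len(nv), excl), 1)
    }
  list(es = es, neg = matrix(cand, n_edges, n_neg))
}

# Monte-Carlo graph log-likelihood per sampled edge (mean), with signs
# carried over to the negatives; optionally the gradient wrt V.
graph_ll_core <- function(model, V, mb, grad = FALSE) {
  ed <- model$edges
  ii <- ed$i[mb$es]; jj <- ed$j[mb$es]; ss <- ed$sign[mb$es]
  z_pos <- rowSums(V[ii, , drop = FALSE] * V[jj, , drop = FALSE])
  ll <- sum(log_sigmoid(ss * z_pos))
  dV <- if (grad) matrix(0, nrow(V), ncol(V)) else NULL
  if (grad) {
    coef <- (1 - sigmoid(ss * z_pos)) * ss # d/dz of log sigmoid(s z)
    dV <- accum_rows(dV, ii, coef * V[jj, , drop = FALSE])
    dV <- accum_rows(dV, jj, coef * V[ii, , drop = FALSE])
  }
  for (q in seq_len(ncol(mb$neg))) {
    jn <- mb$neg[, q]
    z_neg <- rowSums(V[ii, , drop = FALSE] * V[jn, , drop = FALSE])
    ll <- ll + sum(log_sigmoid(-ss * z_neg))
    if (grad) {
      coefn <- -sigmoid(ss * z_neg) * ss
      dV <- accum_rows(dV, ii, coefn * V[jn, , drop = FALSE])
      dV <- accum_rows(dV, jn, coefn * V[ii, , drop = FALSE])
    }
  }
  n_terms <- length(mb$es)
  list(ll = ll / n_terms, dV = if (grad) dV / n_terms else NULL)
}

# Accumulate rows of `add` into rows `idx` of `m` (with repeats).
accum_rows <- function(m, idx, add) {
  r <- rowsum(add, group = idx)
  rows <- as.integer(rownames(r))
  m[rows, ] <- m[rows, , drop = FALSE] + r
  m
}

#' Monte-Carlo estimate of the guidance-graph log-likelihood
#'
#' Samples edges with probability proportional to their weights,
#' accumulates `log sigmoid(s_ij v_i' v_j)` for each, and for `n_neg`
#' negative vertices per edge (drawn from outside the neighbourhood of
#' `i`, inheriting the edge's sign) accumulates
#' `log(1 - sigmoid(s_ij v_i' v_j'))`. Deterministic given `seed`.
#'
#' @param model A [glue_model()].
#' @param V Feature embedding matrix (vertices x m), e.g. a posterior
#'   sample or mean.
#' @param n_edges Number of edges to sample (default: all edges once per
#'   unit weight in expectation, i.e. the edge count).
#' @param n_neg Negatives per edge.
#' @param seed Integer seed.
#' @return Mean log-likelihood per sampled edge.
#' @export
graph_log_likelihood <- function(model, V, n_edges = NULL, n_neg = 1,
                                 seed = 1) {
  stopifnot(n_neg >= 1)
  n_edges <- n_edges %||% length(model$edges$i)
  with_seed(seed, {
    mb <- sample_graph_minibatch(model, n_edges, n_neg)
    graph_ll_core(model, V, mb)$ll
  })
}
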