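# Minimal dense neural-network machinery: multilayer perceptrons with
# leaky-rectifier activations, explicit forward caches, hand-derived
# backward passes, and an RMSprop optimiser (no momentum). All encoder,
# discriminator and graph-convolution gradients in the package flow
# through these functions; they are verified against finite differences
# in the test suite.

LRELU_SLOPE <- 0.2

# He-style initialisation.
init_mat <- function(nin, nout, scale = sqrt(2 / nin)) {
  matrix(rnorm(nin * nout, sd = scale), nin, nout)
}

# An MLP "core": `depth` hidden layers of width `h`.
mlp_init <- function(d_in, h, depth = 2) {
  W <- list(); b <- list()
  din <- d_in
  for (l in seq_len(depth)) {
    W[[l]] <- init_mat(din, h)
    b[[l]] <- rep(0, h)
    din <- h
  }
  list(W = W, b = b)
}

mlp_forward <- function(core, X) {
  A <- X
  cache <- list(A0 = X, Z = list(), A = list())
  for (l in seq_along(core$W)) {
    Z <- A %*% core$W[[l]] + rep(core$b[[l]], each = nrow(A))
    A <- lrelu(Z, LRELU_SLOPE)
    cache$Z[[l]] <- Z
    cache$A[[l]] <- A
  }
  list(H = A, cache = cache)
}

# dH: gradient wrt the final hidden activations. Returns parameter
# gradients plus the gradient wrt the input rows.
mlp_backward <- function(core, cache, dH) {
  L <- length(core$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dA <- dH
  for (l in rev(seq_len(L))) {
    dZ <- dA * lrelu_grad(cache$Z[[l]], LRELU_SLOPE)
    Aprev <- if (l == 1) cache$A0 else cache$A[[l - 1]]
    gW[[l]] <- crossprod(Aprev, dZ)
    gb[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, core$W[[l]])
  }
  list(W = gW, b = gb, dX = dA)
}

head_init <- function(h, d_out, scale = sqrt(1 / h)) {
  list(W = init_mat(h, d_out, scale), b = rep(0, d_out))
}

head_forward <- function(head, H) H %*% head$W + rep(head$b, each = nrow(H))

head_backward <- function(head, H, dY) {
  list(W = crossprod(H, dY), b = colSums(dY), dH = tcrossprod(dY, head$W))
}

# ---- flat parameter trees ------------------------------------------------

# Apply f to every numeric leaf of a nested list of parameters.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.numeric(t1)) return(do.call(f, trees))
  out <- vector("list", length(t1))
  names(out) <- names(t1)
  for (k in seq_along(t1))
    out[[k]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, k)))
  out
}

tree_zeros <- function(tree) tree_map(function(x) x * 0, tree)

# RMSprop with no momentum: v <- rho v + (1 - rho) g^2;
# p <- p - lr * g / (sqrt(v) + eps). `direction` +1 descends, -1 ascends.
rmsprop_update <- function(params, grads, state, lr, rho = 0.99,
                           eps = 1e-8, direction = 1) {
  if (is.numeric(params)) {
    v <- rho * state + (1 - rho) * grads^2
    list(params = params - direction * lr * grads / (sqrt(v) + eps),
         state = v)
  } else {
    p <- vector("list", length(params)); s <- p
    names(p) <- names(params); names(s) <- names(params)
    for (k in seq_along(params)) {
      u <- rmsprop_update(params[[k]], grads[[k]], state[[k]], lr, rho,
                          eps, direction)
      p[[k]] <- u$params; s[[k]] <- u$state
    }
    list(params = p, state = s)
  }
}

tree_flatten <- function(tree) {
  if (is.numeric(tree)) return(as.numeric(tree))
  unlist(lapply(tree, tree_flatten), use.names = FALSE)
}

tree_unflatten <- function(tree, vec) {
  if (is.numeric(tree)) {
    out <- tree
    out[] <- vec[seq_along(out)]
    return(out)
  }
  res <- vector("list", length(tree)); names(res) <- names(tree)
  pos <- 0
  for (k in seq_along(tree)) {
    n <- length(tree_flatten(tree[[k]]))
    res[[k]] <- tree_unflatten(tree[[k]], vec[pos + seq_len(n)])
    pos <- pos + n
  }
  res
}

# Numerical gradient of scalar-valued f(tree) by central differences
# (test helper for verifying the analytic backward passes).
numeric_grad <- function(f, tree, h = 1e-5) {
  x0 <- tree_flatten(tree)
  g <- numeric(length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xm <- x0
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    g[i] <- (f(tree_unflatten(tree, xp)) - f(tree_unflatten(tree, xm))) /
      (2 * h)
  }
  tree_unflatten(tree, g)
}
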