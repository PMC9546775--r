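# S3 methods for the fitted model object.

#' @export
print.glue_model <- function(x, ...) {
  cat("Graph-guided multi-omics integration model",
      if (isTRUE(x$fitted)) "(fitted)" else "(untrained)", "\n")
  cat(sprintf("  embedding dimension m = %d, hidden width %d\n",
              x$config$m, x$config$hidden))
  for (k in seq_along(x$meta)) {
    mt <- x$meta[[k]]
    cat(sprintf("  layer '%s': %d features, family %s, %d batch(es)\n",
                mt$name, length(mt$features), mt$family, mt$B))
  }
  cat(sprintf("  guidance graph: %d vertices, %d edges\n",
              length(x$vertices), length(x$edges$i)))
  invisible(x)
}

#' @export
summary.glue_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  training: %d epochs over %d stage(s); final val loss %.4f (best %.4f)\n",
                nrow(h), max(h$stage), h$val_loss[nrow(h)],
                min(h$best_val_loss, na.rm = TRUE)))
  }
  if (!is.null(object$balancing_weights)) {
    w <- unlist(object$balancing_weights)
    cat(sprintf("  balancing weights: range [%.3g, %.3g]\n",
                min(w), max(w)))
  }
  invisible(object)
}

#' Predict cell embeddings for (new) data
#'
#' Posterior-mean cell embeddings for the model's layers, or for new
#' [omics_layer()] objects over the same feature spaces (the fitted
#' PCA/LSI front-ends are reapplied).
#'
#' @param object A fitted `glue_model`.
#' @param newdata Optional list of [omics_layer()]s; default: the
#'   training layers.
#' @param ... Unused.
#' @return Named list of embedding matrices.
#' @export
predict.glue_model <- function(object, newdata = NULL, ...) {
  layers <- newdata %||% attr(object, "layers")
  out <- list()
  for (k in seq_along(object$meta)) {
    ly <- layers[[k]]
    if (!identical(ly$features, object$meta[[k]]$features))
      stop("predict: feature list mismatch for layer '", ly$name, "'")
    red <- ly$reduced %||%
      apply_reduction(attr(object, "layers")[[k]]$reduction, ly$X)
    out[[object$meta[[k]]$name]] <- encoder_forward(object, k, red)$mean
  }
  out
}

#' Feature embeddings of a fitted model
#'
#' @param object A fitted `glue_model`.
#' @param ... Unused.
#' @return The vertices x m posterior-mean feature embedding matrix
#'   (analogous to a loading matrix).
#' @export
coef.glue_model <- function(object, ...) {
  V <- graph_encoder_forward(object)$mean
  rownames(V) <- object$vertices
  V
}

#' Plot the training history
#'
#' Validation loss per epoch, stage boundaries marked.
#'
#' @param x A fitted `glue_model`.
#' @param ... Passed to [plot()].
#' @export
plot.glue_model <- function(x, ...) {
  if (is.null(x$history)) stop("plot: model has no training history")
  h <- x$history
  plot(seq_len(nrow(h)), h$val_loss, type = "l", xlab = "epoch",
       ylab = "validation loss", ...)
  b <- which(diff(h$stage) != 0)
  if (length(b)) graphics::abline(v = b + 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' Simulate data from the fitted decoders
#'
#' Draws reconstructed observations for each layer: cells are encoded to
#' posterior means, decoded through the layer's generative family, and
#' sampled (NB counts at the observed library sizes; ZILN levels).
#'
#' @param object A fitted `glue_model`.
#' @param nsim Number of replicate draws.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List (length `nsim`) of per-layer simulated matrices.
#' @export
simulate.glue_model <- function(object, nsim = 1, seed = 1, ...) {
  layers <- attr(object, "layers")
  emb <- predict(object)
  V <- coef(object)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      out <- list()
      for (k in seq_along(object$meta)) {
        mt <- object$meta[[k]]
        ly <- layers[[k]]
        dec <- object$params$dec[[k]]
        Vk <- V[mt$vidx, , drop = FALSE]
        bb <- ly$batches
        if (mt$family == "NB") {
          tot <- pmax(Matrix::rowSums(ly$X), 1)
          mu <- nb_decode(emb[[k]], Vk, dec, bb, tot)
          theta <- exp(dec$logtheta)[bb, , drop = FALSE]
          x <- matrix(rnbinom(length(mu), size = as.vector(theta),
                              mu = as.vector(mu)), nrow(mu))
        } else {
          muz <- ziln_decode(emb[[k]], Vk, dec, bb)
          sig <- exp(dec$logsigma)[bb, , drop = FALSE]
          del <- sigmoid(dec$logitdelta)[bb, , drop = FALSE]
          x <- exp(matrix(rnorm(length(muz), as.vector(muz),
                                as.vector(sig)), nrow(muz)))
          x[matrix(runif(length(x)), nrow(x)) < del] <- 0
        }
        dimnames(x) <- dimnames(as.matrix(ly$X))
        out[[mt$name]] <- x
      }
      out
    })
  })
}

#' @export
print.glue_config <- function(x, ...) {
  cat("Integration model configuration:\n")
  flat <- x[!vapply(x, is.null, TRUE)]
  for (nm in names(flat))
    cat(sprintf("  %-20s %s\n", nm, paste(format(flat[[nm]]), collapse = " ")))
  invisible(x)
}
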