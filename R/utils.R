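#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod tcrossprod
#' @importFrom methods as is
#' @importFrom stats rnorm runif rbinom rnbinom rlnorm kmeans cor p.adjust
#'   prcomp quantile median sd var dist fisher.test simulate setNames
#' @importFrom graphics abline
#' @importFrom utils head read.table write.table modifyList
NULL

# Row-wise softmax of a dense matrix, numerically stabilised.
softmax_rows <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# leaky rectifier; for slope < 1 this is simply the elementwise max
lrelu <- function(z, slope = 0.2) pmax(z, slope * z)
lrelu_grad <- function(z, slope = 0.2) slope + (1 - slope) * (z > 0)

# Run code under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible child seed from a base seed (keeps within 32-bit range).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (seed * 48271 + k * 10007) %% 2147483563L
}

l2_normalize_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}

cosine_rows <- function(a, b) {
  # cosine similarity between corresponding rows of a and b
  rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
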