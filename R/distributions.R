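#' Negative binomial log-probability
#'
#' Elementwise log-probability of non-negative integer observations under the
#' negative binomial distribution parameterised by mean `mu` and inverse
#' dispersion `theta` (variance `mu + mu^2 / theta`), computed with log-gamma
#' arithmetic so that it stays finite for arbitrarily large counts:
#'
#' \deqn{\log NB(x; \mu, \theta) = \log\Gamma(x+\theta) - \log\Gamma(\theta)
#'   - \log\Gamma(x+1) + x \log\frac{\mu}{\theta+\mu}
#'   + \theta \log\frac{\theta}{\theta+\mu}.}
#'
#' As \eqn{\theta \to \infty} the distribution approaches Poisson(`mu`).
#'
#' @param x Non-negative integer vector (or matrix) of counts.
#' @param mu Positive vector/matrix of means, recycled against `x`.
#' @param theta Positive vector/matrix of inverse dispersions.
#' @param sum If `TRUE` (default) return the total log-probability, otherwise
#'   the elementwise values.
#' @return A single number (or numeric array when `sum = FALSE`).
#' @examples
#' nb_log_prob(c(0, 3, 10), mu = c(1, 2, 5), theta = c(2, 2, 2))
#' @export
nb_log_prob <- function(x, mu, theta, sum = TRUE) {
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("nb_log_prob: x must contain non-negative integers")
  if (any(mu <= 0) || any(theta <= 0))
    stop("nb_log_prob: mu and theta must be strictly positive")
  lp <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    x * (log(mu) - log(theta + mu)) +
    theta * (log(theta) - log(theta + mu))
  if (sum) base::sum(lp) else lp
}

# Gradients of the summed NB log-probability with respect to mu and theta.
nb_log_prob_grad <- function(x, mu, theta) {
  list(
    dmu = x / mu - (x + theta) / (theta + mu),
    dtheta = digamma(x + theta) - digamma(theta) +
      log(theta) + 1 - log(theta + mu) - (x + theta) / (theta + mu)
  )
}

#' Zero-inflated log-normal log-probability
#'
#' Log-probability of non-negative observations under a zero-inflated
#' log-normal model: an observation is exactly zero with probability `delta`,
#' and otherwise follows a log-normal distribution with log-scale mean `mu`
#' and log-scale standard deviation `sigma`:
#'
#' \deqn{p(x) = \delta \; [x = 0] \; + \; (1-\delta)\,
#'   \mathrm{LN}(x;\mu,\sigma)\; [x > 0].}
#'
#' This is the decoder family used for per-gene DNA methylation levels, where
#' zeros are dropouts (uncovered genes) rather than measured absence.
#'
#' @param x Non-negative numeric vector/matrix.
#' @param mu Real log-scale means.
#' @param sigma Positive log-scale standard deviations.
#' @param delta Zero-inflation probabilities, strictly inside (0, 1) (exact 0
#'   or 1 is accepted and handled by limits).
#' @param sum If `TRUE` (default) return the total log-probability.
#' @return A single number (or numeric array when `sum = FALSE`).
#' @examples
#' ziln_log_prob(c(0, 1, 2.5), mu = c(0, 0, 1), sigma = c(1, 1, 1),
#'               delta = c(0.3, 0.3, 0.3))
#' @export
ziln_log_prob <- function(x, mu, sigma, delta, sum = TRUE) {
  if (any(x < 0)) stop("ziln_log_prob: x must be non-negative")
  if (any(sigma <= 0)) stop("ziln_log_prob: sigma must be strictly positive")
  if (any(delta < 0) || any(delta > 1))
    stop("ziln_log_prob: delta must lie in [0, 1]")
  x <- x + 0 # promote logical/integer
  lp <- numeric(length(x))
  z <- x == 0
  lp[z] <- log(delta[z] + (delta[z] == 0) * 0) # log(0) = -Inf intended
  if (any(!z)) {
    xi <- x[!z]
    lp[!z] <- log1p(-delta[!z]) - log(xi) - log(sigma[!z]) -
      0.5 * log(2 * pi) - (log(xi) - mu[!z])^2 / (2 * sigma[!z]^2)
  }
  dim(lp) <- dim(x)
  if (sum) base::sum(lp) else lp
}

# Gradients of the summed ZILN log-probability wrt mu, sigma, delta.
ziln_log_prob_grad <- function(x, mu, sigma, delta) {
  z <- x == 0
  dmu <- dsig <- ddel <- numeric(length(x))
  ddel[z] <- 1 / delta[z]
  if (any(!z)) {
    r <- (log(x[!z]) - mu[!z]) / sigma[!z]^2
    dmu[!z] <- r
    dsig[!z] <- -1 / sigma[!z] + r^2 * sigma[!z]
    ddel[!z] <- -1 / (1 - delta[!z])
  }
  dim(dmu) <- dim(dsig) <- dim(ddel) <- dim(x)
  list(dmu = dmu, dsigma = dsig, ddelta = ddel)
}

#' KL divergence of a diagonal normal from the standard normal
#'
#' Closed-form \eqn{KL(N(\mu, \mathrm{diag}(\sigma^2)) \,\|\, N(0, I))}
#' summed over dimensions:
#' \eqn{\tfrac12 \sum_d (\sigma_d^2 + \mu_d^2 - 1 - \log \sigma_d^2)}.
#'
#' @param mean Numeric vector or matrix (rows = independent posteriors).
#' @param logvar Log-variances, same shape as `mean`.
#' @return If `mean` is a matrix, a vector of per-row KL values; otherwise a
#'   single number.
#' @export
kl_diag_normal <- function(mean, logvar) {
  kl <- 0.5 * (exp(logvar) + mean^2 - 1 - logvar)
  if (is.matrix(mean)) rowSums(kl) else base::sum(kl)
}

# Gradients of total KL wrt mean and logvar (elementwise).
kl_diag_normal_grad <- function(mean, logvar) {
  list(dmean = mean, dlogvar = 0.5 * (exp(logvar) - 1))
}
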