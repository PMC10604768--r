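#' Evidence lower bound loss for one sample
#'
#' The training objective is the negative ELBO: a reconstruction term plus
#' `beta` times the closed-form KL divergence of the diagonal-Gaussian
#' variational posterior `N(mu, exp(logvar))` from the standard-normal prior,
#' `kl = -1/2 * sum(1 + logvar - mu^2 - exp(logvar))`.  The reconstruction
#' term is sum-of-squared-errors / 2 (Gaussian likelihood, the default for
#' min-max scaled BOLD windows) or binary cross-entropy (Bernoulli).
#' Minimizing `total` maximizes the ELBO.
#'
#' @param x Input matrix (or vector).
#' @param x_hat Reconstruction, same shape; must lie in \[0, 1\] for the
#'   Bernoulli likelihood.
#' @param mu,logvar Latent Gaussian parameters (vectors of equal length).
#' @param beta KL weight (1 recovers the plain ELBO).
#' @param recon_likelihood `"gaussian"` or `"bernoulli"`.
#' @return List with `total`, `recon_term`, `kl_term`.
#' @examples
#' elbo_loss(matrix(0.5, 2, 2), matrix(0.5, 2, 2), mu = c(1), logvar = c(0))
#' @export
elbo_loss <- function(x, x_hat, mu, logvar, beta = 1,
                      recon_likelihood = c("gaussian", "bernoulli")) {
  recon_likelihood <- match.arg(recon_likelihood)
  assert_that(all(dim(as.matrix(x)) == dim(as.matrix(x_hat))),
              "x and x_hat must have the same shape")
  assert_that(length(mu) == length(logvar),
              "mu and logvar must have the same length")
  kl <- kl_gaussian(mu, logvar)
  if (recon_likelihood == "gaussian") {
    recon <- 0.5 * sum((x - x_hat)^2)
  } else {
    if (any(x_hat < 0 | x_hat > 1)) {
      stop_fc("bernoulli likelihood requires x_hat in [0, 1]")
    }
    eps <- 1e-7
    xh <- pmin(pmax(x_hat, eps), 1 - eps)
    recon <- -sum(x * log(xh) + (1 - x) * log(1 - xh))
  }
  list(total = recon + beta * kl, recon_term = recon, kl_term = kl)
}

# closed-form KL( N(mu, diag exp(logvar)) || N(0, I) ), always >= 0
kl_gaussian <- function(mu, logvar) {
  -0.5 * sum(1 + logvar - mu^2 - exp(logvar))
}

# batched gradient of mean per-sample loss wrt x_hat, mu, logvar
elbo_grad_batch <- function(X, Xh, mu, logvar, beta, recon_likelihood) {
  N <- dim(X)[1]
  if (recon_likelihood == "gaussian") {
    dxh <- (Xh - X) / N
  } else {
    eps <- 1e-7
    xh <- pmin(pmax(Xh, eps), 1 - eps)
    dxh <- (-(X / xh) + (1 - X) / (1 - xh)) / N
  }
  list(dxh = dxh,
       dmu = beta * mu / N,
       dlv = beta * 0.5 * (exp(logvar) - 1) / N)
}

elbo_value_batch <- function(X, Xh, mu, logvar, beta, recon_likelihood) {
  N <- dim(X)[1]
  if (recon_likelihood == "gaussian") {
    recon <- 0.5 * sum((X - Xh)^2) / N
  } else {
    eps <- 1e-7
    xh <- pmin(pmax(Xh, eps), 1 - eps)
    recon <- -sum(X * log(xh) + (1 - X) * log(1 - xh)) / N
  }
  kl <- sum(-0.5 * (1 + logvar - mu^2 - exp(logvar))) / N
  c(total = recon + beta * kl, recon = recon, kl = kl)
}
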