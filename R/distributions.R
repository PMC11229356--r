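#' Reparameterized logistic-normal sample
#'
#' `softmax(mu + sqrt(var) * noise)` row-wise: a draw from the
#' logistic-normal distribution given standard-normal noise, mapping the
#' Gaussian latent onto the probability simplex.  Invariant to adding a
#' constant to every coordinate of `mu` (softmax shift invariance).
#'
#' @param mu numeric matrix (cells x k), pre-softmax Gaussian means
#' @param var positive matrix (or scalar), pre-softmax Gaussian variances
#' @param noise standard-normal noise of the same shape as `mu` (zeros give
#'   the deterministic embedding pathway)
#' @return matrix of simplex rows (non-negative, summing to 1)
#' @examples
#' sampleLogisticNormal(matrix(0, 1, 4), 1, matrix(0, 1, 4))  # uniform 1/4
#' @export
sampleLogisticNormal <- function(mu, var, noise) {
  mu <- as.matrix(mu)
  if (any(var <= 0)) stop("sampleLogisticNormal: var must be positive")
  softmaxRows(mu + sqrt(var) * as.matrix(noise))
}

#' Diagonal-Gaussian Kullback-Leibler divergence
#'
#' Closed-form `KL(N(mu, var) || N(priorMu, priorVar))` summed over columns,
#' one value per row.  Used for the latent variable (standard-normal prior
#' on the pre-softmax coordinates) and for the log size factors
#' (batch-indexed log-normal priors).  Always non-negative; zero iff
#' posterior equals prior.
#'
#' @param mu,var posterior means and variances (matrix or vector)
#' @param priorMu,priorVar prior means and variances (recycled)
#' @return numeric vector, one KL per row
#' @examples
#' klDiagGaussian(1, 1)  # 0.5
#' @export
klDiagGaussian <- function(mu, var, priorMu = 0, priorVar = 1) {
  mu <- as.matrix(mu); var <- as.matrix(var)
  if (any(var <= 0) || any(priorVar <= 0))
    stop("klDiagGaussian: variances must be positive")
  kl <- 0.5 * ((var + (mu - priorMu)^2) / priorVar - 1 +
               log(priorVar) - log(var))
  .rowSums(kl, nrow(kl), ncol(kl))
}
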