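#' Negative binomial log-likelihood (mean/dispersion parameterisation)
#'
#' \deqn{\log P(x) = \log\Gamma(x+\theta) - \log\Gamma(\theta) -
#'   \log\Gamma(x+1) + \theta\log\frac{\theta}{\theta+\mu} +
#'   x\log\frac{\mu}{\theta+\mu}}
#'
#' Used for raw gene-expression counts and, as a continuous log-Gamma
#' relaxation, for min-shifted CLR antibody-tag values (see
#' [shiftNonNegative()]).  Vectorised and numerically stable for large
#' \eqn{x} and \eqn{\theta}.
#'
#' @param x counts (or non-negative reals under the continuous relaxation)
#' @param mu positive means
#' @param theta positive dispersions (larger = closer to Poisson)
#' @return element-wise log-likelihood, same shape as `x`
#' @examples
#' nbLogLik(0, 1, 1)  # log(1/2)
#' @export
nbLogLik <- function(x, mu, theta) {
  if (any(!is.finite(x)) || any(!is.finite(mu)) || any(!is.finite(theta)))
    stop("nbLogLik: non-finite inputs")
  if (any(x < 0) || any(mu <= 0) || any(theta <= 0))
    stop("nbLogLik: require x >= 0, mu > 0, theta > 0")
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' Negative multinomial log-likelihood of a whole feature profile
#'
#' Jointly models a cell's entire (binarized) chromatin-accessibility
#' profile: given feature probabilities `p` plus a residual probability `p0`
#' (together summing to one) and overdispersion `r`,
#' \deqn{\log P(x) = \log\Gamma(r+\textstyle\sum_i x_i) - \log\Gamma(r) -
#'   \sum_i \log\Gamma(x_i+1) + r\log p_0 + \sum_i x_i \log p_i}
#'
#' @param x non-negative count vector over features
#' @param p probability vector over features (excluding the residual)
#' @param p0 residual probability; `p0 + sum(p)` must equal 1 within 1e-6
#' @param r positive overdispersion
#' @return scalar log-likelihood
#' @export
negMultinomLogLik <- function(x, p, p0, r) {
  if (any(x < 0)) stop("negMultinomLogLik: x must be non-negative")
  if (r <= 0) stop("negMultinomLogLik: r must be positive")
  if (abs(p0 + sum(p) - 1) > 1e-6)
    stop("negMultinomLogLik: probabilities must sum to 1 (p0 + sum(p))")
  s <- sum(x)
  lgamma(r + s) - lgamma(r) - sum(lgamma(x + 1)) +
    r * log(p0) + sum(x * log(p))
}

#' Shift rows to be non-negative
#'
#' CLR-transformed antibody-tag values are real-valued but enter a count
#' likelihood via a continuous log-Gamma relaxation; each row is shifted by
#' its minimum (if negative) so all values are non-negative.  Isolated here
#' so the convention lives in one place.
#'
#' @param x numeric matrix
#' @return matrix with `pmin(row) >= 0`
#' @export
shiftNonNegative <- function(x) {
  x <- as.matrix(x)
  shift <- pmin(apply(x, 1L, min), 0)
  x - shift
}
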