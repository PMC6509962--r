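# Multivariate density helpers. All evaluation is Cholesky-based; covariance
# arguments must already be positive definite (see regularize_covariance).

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Row-wise log N(x | mu, Sigma) for an n x D matrix.
dmvnorm_log <- function(x, mu, sigma) {
  x <- rbind(x)
  d <- ncol(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  q <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

## Row-wise log multivariate-t with location mu, scale sigma, df degrees of
## freedom (density of mu + T where T ~ t_df(0, sigma)).
dmvt_log <- function(x, mu, sigma, df) {
  x <- rbind(x)
  d <- ncol(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  q <- colSums(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(ch))) - ((df + d) / 2) * log1p(q / df)
}

#' Sufficient statistics of a set of profiles
#'
#' Collapses an m x D matrix of profiles into the statistics needed by the
#' conjugate normal-inverse-Wishart updates: the member count, the coordinate
#' sums and the sum of outer products. An empty matrix (m = 0) is valid and
#' yields the prior-predictive limit in [niw_predictive_logdensity()].
#'
#' @param y Numeric matrix with one row per profile, or `NULL` for an empty
#'   class (in which case `d` must be given).
#' @param d Number of fractions; inferred from `y` when possible.
#' @return A list with elements `count`, `sum` (length-D) and `squares`
#'   (D x D sum of outer products).
#' @export
class_sufficient_stats <- function(y = NULL, d = NULL) {
  if (is.null(y) || (is.matrix(y) && nrow(y) == 0L)) {
    if (is.null(d)) stop("'d' must be given for an empty class")
    return(list(count = 0L, sum = numeric(d), squares = matrix(0, d, d)))
  }
  y <- rbind(y)
  list(count = nrow(y), sum = colSums(y), squares = crossprod(y))
}

#' Posterior-predictive log density of one profile under a class
#'
#' With a normal-inverse-Wishart prior and the Gaussian class members
#' summarised by their sufficient statistics, the posterior predictive of a
#' new profile is a multivariate t. With zero members this reduces to the
#' prior predictive: a t with `nu0 - D + 1` degrees of freedom located at
#' `mu0`. This is the per-class density used inside the collapsed Gibbs
#' sampler.
#'
#' @param x Numeric vector (one profile) or matrix of profiles (rows).
#' @param stats Class sufficient statistics from [class_sufficient_stats()].
#' @param priors A `tagm_priors` object (see [default_priors()]).
#' @return Log predictive density, one value per row of `x`.
#' @export
niw_predictive_logdensity <- function(x, stats, priors) {
  x <- rbind(x)
  d <- ncol(x)
  m <- stats$count
  lambda_m <- priors$lambda0 + m
  nu_m <- priors$nu0 + m
  mu_m <- (priors$lambda0 * priors$mu0 + stats$sum) / lambda_m
  s_m <- priors$S0 + stats$squares +
    priors$lambda0 * tcrossprod(priors$mu0) - lambda_m * tcrossprod(mu_m)
  s_m <- (s_m + t(s_m)) / 2
  df <- nu_m - d + 1
  scale <- s_m * (lambda_m + 1) / (lambda_m * df)
  scale <- regularize_covariance(scale, quiet = TRUE)
  dmvt_log(x, mu_m, scale, df)
}
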