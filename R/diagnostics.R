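# Convergence diagnostics for scalar chain summaries. These are diagnostics
# only: they can flag non-convergence but cannot guarantee convergence, and
# downstream analysis should never rest on chains that fail them.

## Spectral density at frequency zero, estimated by fitting an
## autoregressive model with order selected by AIC. Used for the
## time-series standard errors of the Geweke test and series summaries.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares the between-chain and within-chain variances of a scalar summary
#' across parallel chains; their ratio (the potential scale reduction
#' factor, R-hat) should be close to one for converged chains, and values
#' below about 1.2 are commonly treated as acceptable. The corrected
#' estimator with its sampling-variability adjustment is used, and the 97.5%
#' upper confidence bound is derived from the F distribution of the
#' between/within variance ratio. An optional log transform can improve the
#' normality of positive-valued summaries.
#'
#' @param series_list List of at least two equal-length series
#'   (`tagm_series` or numeric vectors) of the same statistic.
#' @param transform `"none"` or `"log"`.
#' @return A `tagm_gelman` object with `point_estimate` and `upper_ci`.
#' @export
gelman_rubin <- function(series_list, transform = c("none", "log")) {
  transform <- match.arg(transform)
  xs <- lapply(series_list, series_values)
  m <- length(xs)
  if (m < 2L) stop("at least two chains are required")
  t_len <- unique(lengths(xs))
  if (length(t_len) != 1L) stop("all series must have equal length")
  if (t_len < 4L) stop("series too short (need T >= 4)")
  if (transform == "log") {
    if (any(vapply(xs, function(x) any(x <= 0), TRUE)))
      stop("log transform requires strictly positive values")
    xs <- lapply(xs, log)
  }
  x <- matrix(unlist(xs), ncol = m)
  t_n <- nrow(x)
  s2 <- apply(x, 2L, stats::var)
  w <- mean(s2)
  if (w == 0) stop("zero within-chain variance in all chains")
  xbar <- colMeans(x)
  b <- t_n * stats::var(xbar)
  muhat <- mean(xbar)
  var_w <- stats::var(s2) / m
  var_b <- (2 * b^2) / (m - 1)
  cov_wb <- (t_n / m) * (stats::cov(s2, xbar^2) -
                           2 * muhat * stats::cov(s2, xbar))
  v_hat <- (t_n - 1) * w / t_n + (1 + 1 / m) * b / t_n
  var_v <- ((t_n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
              2 * (t_n - 1) * (1 + 1 / m) * cov_wb) / t_n^2
  df_v <- (2 * v_hat^2) / var_v
  df_adj <- (df_v + 3) / (df_v + 1)
  b_df <- m - 1
  w_df <- (2 * w^2) / var_w
  r2_fixed <- (t_n - 1) / t_n
  r2_random <- (1 + 1 / m) * (1 / t_n) * (b / w)
  psrf <- sqrt(df_adj * (r2_fixed + r2_random))
  upper <- sqrt(df_adj * (r2_fixed +
                            stats::qf(0.975, b_df, w_df) * r2_random))
  structure(list(point_estimate = psrf, upper_ci = upper,
                 transform = transform, n_chains = m, n_samples = t_n),
            class = "tagm_gelman")
}

#' @export
print.tagm_gelman <- function(x, ...) {
  cat("Potential scale reduction factor:\n")
  cat("  Point est.:", format(x$point_estimate, digits = 3),
      "  Upper C.I.:", format(x$upper_ci, digits = 3), "\n")
  invisible(x)
}

#' Geweke first/last-window convergence test
#'
#' For each chain independently, tests whether the mean of the first
#' `frac_first` fraction of the series differs from the mean of the last
#' `frac_last` fraction. Window variances are estimated by the spectral
#' density at frequency zero (AR fit, AIC order selection), so
#' autocorrelation is accounted for. A small p-value is evidence that the
#' chain has not converged.
#'
#' @param series_list List of series (`tagm_series` or numeric vectors).
#' @param frac_first,frac_last Window fractions; must not overlap
#'   (`frac_first + frac_last <= 1`).
#' @return A data frame with one row per chain: `chain`, `z_value`,
#'   `p_value` (two-sided).
#' @export
geweke_test <- function(series_list, frac_first = 0.1, frac_last = 0.5) {
  if (frac_first <= 0 || frac_last <= 0 || frac_first + frac_last > 1)
    stop("window fractions must be positive and sum to at most 1")
  xs <- lapply(series_list, series_values)
  res <- lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    t_n <- length(x)
    n1 <- floor(frac_first * t_n)
    n2 <- floor(frac_last * t_n)
    if (n1 < 2L || n2 < 2L) stop("series too short for the chosen windows")
    x1 <- x[seq_len(n1)]
    x2 <- x[(t_n - n2 + 1L):t_n]
    v1 <- spectrum0_ar(x1)
    v2 <- spectrum0_ar(x2)
    if (v1 == 0 && v2 == 0) stop("zero-variance windows")
    z <- (mean(x1) - mean(x2)) / sqrt(v1 / n1 + v2 / n2)
    data.frame(chain = i, z_value = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, res)
}

#' Numerical summary of a diagnostic series
#'
#' Empirical mean and standard deviation, the naive standard error of the
#' mean (`sd / sqrt(T)`), the autocorrelation-adjusted time-series standard
#' error (spectral density at frequency zero over T), and the
#' 2.5/25/50/75/97.5% quantiles (type-7 interpolation).
#'
#' @param series A `tagm_series` or numeric vector with at least 2 values.
#' @return A list with `mean`, `sd`, `naive_se`, `timeseries_se`,
#'   `quantiles`.
#' @export
series_summary <- function(series) {
  x <- series_values(series)
  t_n <- length(x)
  if (t_n < 2L) stop("series must contain at least two samples")
  list(mean = mean(x), sd = stats::sd(x),
       naive_se = stats::sd(x) / sqrt(t_n),
       timeseries_se = sqrt(spectrum0_ar(x) / t_n),
       quantiles = stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975),
                                   type = 7))
}

#' Advisory convergence flag
#'
#' `TRUE` when the Gelman-Rubin point estimate is strictly below the
#' threshold (1.2 by default). Advisory only: a passing value is consistent
#' with convergence but does not prove it.
#'
#' @param gelman_result A `tagm_gelman` object.
#' @param threshold Strict upper bound on R-hat.
#' @export
flag_convergence <- function(gelman_result, threshold = 1.2) {
  stopifnot(inherits(gelman_result, "tagm_gelman"))
  gelman_result$point_estimate < threshold
}
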