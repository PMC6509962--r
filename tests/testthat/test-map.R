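# EM inference: log-posterior correctness against an independent
# term-by-term oracle, monotonicity, parameter recovery, and the
# responsibility conventions of map_predict.

## independent log-posterior computation: plain loops, mclust densities for
## the Gaussians, det/solve arithmetic for every prior term
oracle_log_posterior <- function(params, dataset, priors, spec) {
  x <- dataset$x
  n <- nrow(x)
  d <- ncol(x)
  k <- length(dataset$classes)
  eps <- params$outlier_weight
  total <- 0
  for (i in seq_len(n)) {
    if (dataset$unknown[i]) {
      acc <- 0
      for (j in seq_len(k)) {
        acc <- acc + params$weights[j] * (1 - eps) *
          mclust::dmvnorm(rbind(x[i, ]), params$means[j, ],
                          params$covariances[, , j]) +
          params$weights[j] * eps *
            exp(mvt_loglik_direct(x[i, ], spec$location, spec$scale,
                                  spec$df))
      }
      total <- total + log(acc)
    } else {
      j <- match(dataset$markers[i], dataset$classes)
      total <- total + log(params$weights[j]) + log(1 - eps) +
        log(mclust::dmvnorm(rbind(x[i, ]), params$means[j, ],
                            params$covariances[, , j]))
    }
  }
  for (j in seq_len(k)) {
    sig <- params$covariances[, , j]
    dm <- params$means[j, ] - priors$mu0
    total <- total - 0.5 * (d * log(2 * pi) - d * log(priors$lambda0) +
      log(det(sig)) +
      priors$lambda0 * drop(t(dm) %*% solve(sig) %*% dm))
    lmvg <- (d * (d - 1) / 4) * log(pi) +
      sum(lgamma(priors$nu0 / 2 + (1 - seq_len(d)) / 2))
    total <- total + (priors$nu0 / 2) * log(det(priors$S0)) -
      (priors$nu0 * d / 2) * log(2) - lmvg -
      ((priors$nu0 + d + 1) / 2) * log(det(sig)) -
      0.5 * sum(diag(priors$S0 %*% solve(sig)))
  }
  total <- total + lgamma(sum(priors$beta0)) - sum(lgamma(priors$beta0)) +
    sum((priors$beta0 - 1) * log(params$weights))
  total + lgamma(priors$u + priors$v) - lgamma(priors$u) -
    lgamma(priors$v) + (priors$u - 1) * log(eps) +
    (priors$v - 1) * log(1 - eps)
}

test_that("log posterior matches an independent term-by-term oracle", {
  ds <- tiny_instance()
  priors <- default_priors(ds)
  spec <- outlier_component(ds)
  fit <- map_train(ds, priors, spec, num_iter = 5)
  got <- tagm_log_posterior(fit, ds, priors, spec)
  want <- oracle_log_posterior(fit, ds, priors, spec)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("consistent rescaling shifts the log posterior by its analytic constant", {
  ds <- tiny_instance()
  priors <- default_priors(ds)
  spec <- outlier_component(ds)
  fit <- map_train(ds, priors, spec, num_iter = 3)
  lp1 <- tagm_log_posterior(fit, ds, priors, spec)

  cc <- 1.7
  n <- nrow(ds$x)
  d <- ncol(ds$x)
  k <- length(ds$classes)
  ds2 <- validate_dataset(ds$x * cc, ds$markers)
  priors2 <- priors
  priors2$mu0 <- priors$mu0 * cc
  priors2$S0 <- priors$S0 * cc^2
  spec2 <- spec
  spec2$location <- spec$location * cc
  spec2$scale <- spec$scale * cc^2
  fit2 <- fit
  fit2$means <- fit$means * cc
  fit2$covariances <- fit$covariances * cc^2
  lp2 <- tagm_log_posterior(fit2, ds2, priors2, spec2)
  const <- -(n * d + k * d + k * d * (d + 1)) * log(cc)
  expect_equal(lp2 - lp1, const, tolerance = 1e-8)
})

test_that("the EM trace is non-decreasing and respects num_iter", {
  for (seed in 1:3) {
    sim <- simulate_dataset(k = 3, d = 4, n = 150, separation = 3,
                            seed = seed)
    fit <- map_train(sim$dataset, num_iter = 40)
    tr <- fit$log_posteriors
    expect_length(tr, 40)
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  }
  sim <- simulate_dataset(k = 3, d = 4, n = 100, seed = 9)
  fit1 <- map_train(sim$dataset, num_iter = 1)
  expect_length(fit1$log_posteriors, 1)
  expect_true(is.finite(fit1$log_posteriors))
  expect_error(map_train(sim$dataset, num_iter = 0), "at least 1")
})

test_that("well-separated components are recovered close to truth", {
  sim <- simulate_dataset(k = 2, d = 4, n = 4000, marker_frac = 0.2,
                          outlier_frac = 0, separation = 10, seed = 21)
  fit <- map_train(sim$dataset, num_iter = 60)
  ## generating class j maps to the fitted class of the same name
  for (j in 1:2) {
    expect_lt(max(abs(fit$means[j, ] - sim$truth$class_means[j, ])), 0.1)
  }
})

test_that("duplicated fraction columns trigger the collinearity warning but training completes", {
  sim <- simulate_dataset(k = 2, d = 3, n = 80, outlier_frac = 0, seed = 5)
  x <- cbind(sim$dataset$x, dup = sim$dataset$x[, 3])
  ds <- validate_dataset(x, sim$dataset$markers)
  expect_warning(fit <- map_train(ds, num_iter = 10), "co-linearity")
  expect_true(all(is.finite(fit$log_posteriors)))
})

test_that("map_predict responsibilities match brute-force normalisation", {
  ds <- tiny_instance()
  fit <- map_train(ds, num_iter = 10)
  res <- map_predict(ds, fit)
  cp <- attr(res, "class_probabilities")
  expect_equal(rowSums(cp), rep(1, nrow(ds$x)), tolerance = 1e-10)

  eps <- fit$outlier_weight
  spec <- fit$outlier_spec
  for (i in 1:3) {
    xi <- ds$x[4 + i, ]
    dens_a <- dens_b <- numeric(2)
    for (j in 1:2) {
      dens_a[j] <- fit$weights[j] * (1 - eps) *
        mclust::dmvnorm(rbind(xi), fit$means[j, ], fit$covariances[, , j])
      dens_b[j] <- fit$weights[j] * eps *
        exp(mvt_loglik_direct(xi, spec$location, spec$scale, spec$df))
    }
    expect_equal(cp[4 + i, ], dens_a / sum(dens_a), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(res$`tagm.map.outlier`[4 + i],
                 sum(dens_b) / sum(dens_a + dens_b), tolerance = 1e-12)
  }
})

test_that("a protein at a tight niche centre is confidently allocated; a remote one is an outlier", {
  sim <- simulate_dataset(k = 3, d = 4, n = 300, outlier_frac = 0,
                          separation = 8, seed = 13)
  ds <- sim$dataset
  ## append two probe proteins: one at the first class mean, one far away
  probe <- rbind(sim$truth$class_means[1, ],
                 sim$truth$class_means[1, ] + 50)
  x <- rbind(ds$x, probe)
  ds2 <- validate_dataset(x, c(ds$markers, "unknown", "unknown"),
                          protein_ids = c(rownames(ds$x), "at_mean", "far"))
  fit <- map_train(ds2, num_iter = 50)
  res <- map_predict(ds2, fit)
  expect_gt(res["at_mean", "tagm.map.probability"], 0.99)
  expect_lt(res["at_mean", "tagm.map.outlier"], 0.01)
  expect_gt(res["far", "tagm.map.outlier"], 0.99)
  expect_true(res["far", "tagm.map.allocation"] %in% ds2$classes)
})

test_that("marker anchoring keeps a lone marker's class in place", {
  ## one class is anchored by two markers far from everything else; EM must
  ## keep that component there rather than reassigning it
  set.seed(31)
  a <- matrix(rnorm(40, 0), 20, 2)
  b <- matrix(rnorm(40, 6), 20, 2)
  far <- rbind(c(30, 30), c(30.5, 29.5))
  x <- rbind(a, b, far)
  markers <- c(rep("A", 5), rep("unknown", 15),
               rep("B", 5), rep("unknown", 15), "C", "C")
  ds <- validate_dataset(x, markers)
  fit <- map_train(ds, num_iter = 30)
  expect_lt(sqrt(sum((fit$means["C", ] - c(30.25, 29.75))^2)), 1)
  expect_error(map_train(ds, priors = default_priors(ds), num_iter = 30,
                         outlier_spec = outlier_component(ds)), NA)
})
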