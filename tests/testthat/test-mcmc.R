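# Collapsed Gibbs sampler: retention arithmetic, determinism, predictive
# densities against closed forms, posterior correctness against exhaustive
# enumeration, and the summary conventions.

test_that("retention arithmetic follows floor((numIter - burnin) / thin)", {
  sim <- simulate_dataset(k = 2, d = 3, n = 40, seed = 3)
  cases <- list(c(10, 0, 1), c(10, 3, 1), c(11, 3, 2), c(25, 7, 5),
                c(9, 8, 1))
  for (cs in cases) {
    fit <- mcmc_train(sim$dataset, num_iter = cs[1], burnin = cs[2],
                      thin = cs[3], num_chains = 1, seed = 1)
    expect_identical(chain_length(fit[[1]]),
                     as.integer(floor((cs[1] - cs[2]) / cs[3])))
  }
  expect_error(mcmc_train(sim$dataset, num_iter = 5, burnin = 5, thin = 1),
               "burnin")
  expect_error(mcmc_train(sim$dataset, num_iter = 5, burnin = 2, thin = 4),
               "thin")
  fit2 <- mcmc_train(sim$dataset, num_iter = 3, burnin = 1, thin = 1,
                     num_chains = 2, seed = 1)
  expect_length(fit2, 2)
})

test_that("chains are reproducible by seed and differ across chain indices", {
  sim <- simulate_dataset(k = 2, d = 3, n = 50, seed = 8)
  a <- mcmc_train(sim$dataset, num_iter = 60, burnin = 10, thin = 2,
                  num_chains = 2, seed = 99)
  b <- mcmc_train(sim$dataset, num_iter = 60, burnin = 10, thin = 2,
                  num_chains = 2, seed = 99)
  expect_identical(a$chains[[1]]$alloc, b$chains[[1]]$alloc)
  expect_identical(a$chains[[2]]$prob, b$chains[[2]]$prob)
  expect_false(identical(a$chains[[1]]$alloc, a$chains[[2]]$alloc))
  c1 <- mcmc_train(sim$dataset, num_iter = 60, burnin = 10, thin = 2,
                   num_chains = 2, seed = 100)
  expect_false(identical(a$chains[[1]]$alloc, c1$chains[[1]]$alloc))
})

test_that("the NIW posterior predictive matches closed forms", {
  ds <- tiny_instance()
  priors <- default_priors(ds)
  d <- 2

  ## empty class: prior predictive, a t with nu0 - D + 1 df at mu0
  x <- c(0.3, -0.2)
  st0 <- class_sufficient_stats(NULL, d = d)
  got <- niw_predictive_logdensity(x, st0, priors)
  df0 <- priors$nu0 - d + 1
  scale0 <- priors$S0 * (priors$lambda0 + 1) / (priors$lambda0 * df0)
  expect_equal(got, mvt_loglik_direct(x, priors$mu0, scale0, df0),
               tolerance = 1e-12)

  ## D = 1 with two members: hand-computed univariate t
  pr1 <- list(mu0 = 0.5, lambda0 = 0.1, nu0 = 3, S0 = matrix(0.2),
              beta0 = c(1, 1), u = 2, v = 10)
  y <- matrix(c(1, 2), ncol = 1)
  st <- class_sufficient_stats(y)
  lam_m <- 0.1 + 2
  nu_m <- 3 + 2
  mu_m <- (0.1 * 0.5 + 3) / lam_m
  s_m <- 0.2 + (1 + 4) + 0.1 * 0.25 - lam_m * mu_m^2
  df <- nu_m - 1 + 1
  sc <- s_m * (lam_m + 1) / (lam_m * df)
  xx <- 1.7
  hand <- lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) -
    0.5 * log(sc) - (df + 1) / 2 * log(1 + (xx - mu_m)^2 / (sc * df))
  expect_equal(niw_predictive_logdensity(xx, st, pr1), hand,
               tolerance = 1e-10)

  ## large member count with fixed moments: converges to the Gaussian
  m <- 1e5
  mu_emp <- c(1, -1)
  sig_emp <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  st_big <- list(count = m, sum = m * mu_emp,
                 squares = (m - 1) * sig_emp + m * tcrossprod(mu_emp))
  x_eval <- c(1.4, -0.8)
  got_big <- niw_predictive_logdensity(x_eval, st_big, priors)
  want <- log(mclust::dmvnorm(rbind(x_eval), mu_emp, sig_emp))
  expect_equal(got_big, want, tolerance = 1e-3)
})

test_that("Gibbs posterior matches exhaustive enumeration on a tiny instance", {
  ds <- tiny_instance()
  priors <- default_priors(ds)
  spec <- outlier_component(ds)
  exact <- enumerate_tagm_posterior(ds, priors, spec)

  fit <- mcmc_train(ds, priors, spec, num_iter = 21000, burnin = 1000,
                    thin = 1, num_chains = 1, seed = 6)
  fit <- mcmc_process(fit)
  est <- fit$summary$joint
  ch <- fit$chains[[1]]
  for (i in 1:3) {
    for (j in 1:2) {
      se <- sqrt(tagmix:::spectrum0_ar(ch$prob[i, j, ]) / chain_length(ch))
      expect_lt(abs(est[i, j] - exact$class_prob[i, j]),
                3 * se + 1e-4)
    }
    se_o <- sqrt(tagmix:::spectrum0_ar(ch$outlier_prob[, i]) /
                   chain_length(ch))
    expect_lt(abs(mean(ch$outlier[, i]) - exact$outlier_prob[i]),
              4 * se_o + 5e-3)
  }
})

test_that("per-sweep probability rows are normalised and sane", {
  sim <- simulate_dataset(k = 3, d = 4, n = 60, seed = 14)
  fit <- mcmc_train(sim$dataset, num_iter = 40, burnin = 10, thin = 1,
                    num_chains = 1, seed = 2)
  ch <- fit[[1]]
  sums <- apply(ch$prob, c(1, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(ch$outlier_prob >= 0 & ch$outlier_prob <= 1))
  expect_true(all(ch$alloc >= 1 & ch$alloc <= 3))
  expect_true(all(ch$outlier %in% 0:1))
})

test_that("processing computes the documented summaries", {
  ## hand-built chain: one protein, two classes, two samples
  p <- array(0, c(1, 2, 2))
  p[1, , 1] <- c(0.6, 0.4)
  p[1, , 2] <- c(0.8, 0.2)
  ch <- manual_chain(matrix(1L, 2, 1), matrix(0L, 2, 1),
                     matrix(0.1, 2, 1), p, "prot1", c("CA", "CB"))
  params <- manual_chains(list(ch))
  params <- mcmc_process(params)
  s <- params$summary$probabilities
  expect_equal(params$summary$joint[1, ], c(CA = 0.7, CB = 0.3))
  expect_equal(s$`tagm.mcmc.probability`, 0.7)
  expect_identical(s$`tagm.mcmc.allocation`, "CA")
  h1 <- -(0.6 * log(0.6) + 0.4 * log(0.4))
  h2 <- -(0.8 * log(0.8) + 0.2 * log(0.2))
  expect_equal(s$`tagm.mcmc.mean.shannon`, (h1 + h2) / 2, tolerance = 1e-9)
  expect_equal(round(s$`tagm.mcmc.mean.shannon`, 4), 0.5867)

  ## degenerate distribution
  pd <- array(0, c(1, 3, 4))
  pd[1, 1, ] <- 1
  chd <- manual_chain(matrix(1L, 4, 1), matrix(0L, 4, 1),
                      matrix(0, 4, 1), pd, "prot1", c("a", "b", "c"))
  sd_ <- mcmc_process(manual_chains(list(chd)))$summary$probabilities
  expect_equal(sd_$`tagm.mcmc.probability`, 1)
  expect_equal(sd_$`tagm.mcmc.probability.lowerquantile`, 1)
  expect_equal(sd_$`tagm.mcmc.probability.upperquantile`, 1)
  expect_equal(sd_$`tagm.mcmc.mean.shannon`, 0)
})

test_that("shannon entropy follows the closed forms and validates input", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.1, 10)), log(10), tolerance = 1e-9)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.6)), "sum to 1")
})

test_that("prediction tables carry the exact column set and respect flags", {
  sim <- simulate_dataset(k = 3, d = 4, n = 80, seed = 17)
  fit <- mcmc_train(sim$dataset, num_iter = 60, burnin = 20, thin = 2,
                    num_chains = 2, seed = 4)
  res <- mcmc_predict(sim$dataset, fit)
  expect_identical(names(res),
                   c("tagm.mcmc.allocation", "tagm.mcmc.probability",
                     "tagm.mcmc.probability.lowerquantile",
                     "tagm.mcmc.probability.upperquantile",
                     "tagm.mcmc.mean.shannon", "tagm.mcmc.outlier"))
  expect_identical(rownames(res), rownames(sim$dataset$x))

  res_j <- mcmc_predict(sim$dataset, fit, prob_joint = TRUE)
  expect_true(all(paste0("tagm.mcmc.joint.", sim$dataset$classes)
                  %in% names(res_j)))
  jm <- as.matrix(res_j[, paste0("tagm.mcmc.joint.", sim$dataset$classes)])
  expect_equal(unname(rowSums(jm)), rep(1, nrow(jm)), tolerance = 1e-8)

  res_no <- mcmc_predict(sim$dataset, fit, prob_outlier = FALSE)
  expect_false("tagm.mcmc.outlier" %in% names(res_no))

  ## markers are reported with their fixed annotation
  m1 <- which(!sim$dataset$unknown)[1]
  expect_identical(res$`tagm.mcmc.allocation`[m1], sim$dataset$markers[m1])
  expect_equal(res$`tagm.mcmc.probability`[m1], 1)

  other <- simulate_dataset(k = 3, d = 4, n = 90, seed = 18)
  expect_error(mcmc_predict(other$dataset, fit), "different protein set")
})

test_that("per-protein posterior pooling returns row-normalised samples", {
  sim <- simulate_dataset(k = 2, d = 3, n = 50, seed = 20)
  fit <- mcmc_train(sim$dataset, num_iter = 45, burnin = 15, thin = 1,
                    num_chains = 3, seed = 5)
  id <- fit[[1]]$protein_ids[1]
  pp <- protein_posterior(fit, id)
  expect_equal(nrow(pp), 3 * 30)
  expect_equal(unname(rowSums(pp)), rep(1, nrow(pp)), tolerance = 1e-10)
  marker_id <- rownames(sim$dataset$x)[!sim$dataset$unknown][1]
  expect_error(protein_posterior(fit, marker_id), "not among the sampled")
  expect_error(protein_posterior(fit, "nope"), "not among the sampled")
})
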