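# Independent oracles used across the suite. These deliberately avoid the
# package's own density/likelihood code paths: densities come from mclust or
# plain determinant/solve arithmetic, and posteriors from exhaustive
# enumeration of the collapsed model at tiny sizes.

## NIW marginal likelihood of a member matrix Y (possibly 0 rows), computed
## directly from the closed form with base determinant().
niw_marginal_loglik <- function(y, priors) {
  y <- rbind(y)
  d <- length(priors$mu0)
  m <- nrow(y)
  lam0 <- priors$lambda0
  lam_m <- lam0 + m
  nu0 <- priors$nu0
  nu_m <- nu0 + m
  s <- if (m > 0) colSums(y) else numeric(d)
  mu_m <- (lam0 * priors$mu0 + s) / lam_m
  sq <- if (m > 0) t(y) %*% y else matrix(0, d, d)
  s_m <- priors$S0 + sq + lam0 * priors$mu0 %*% t(priors$mu0) -
    lam_m * mu_m %*% t(mu_m)
  s_m <- (s_m + t(s_m)) / 2
  j <- seq_len(d)
  -m * d / 2 * log(pi) + d / 2 * (log(lam0) - log(lam_m)) +
    nu0 / 2 * log(det(priors$S0)) - nu_m / 2 * log(det(s_m)) +
    sum(lgamma((nu_m + 1 - j) / 2) - lgamma((nu0 + 1 - j) / 2))
}

## multivariate-t log density from the textbook formula (det/solve route)
mvt_loglik_direct <- function(x, mu, sigma, df) {
  d <- length(mu)
  q <- drop(t(x - mu) %*% solve(sigma) %*% (x - mu))
  lgamma((df + d) / 2) - lgamma(df / 2) - d / 2 * log(df * pi) -
    0.5 * log(det(sigma)) - (df + d) / 2 * log(1 + q / df)
}

## Exact allocation/outlier posterior for a tiny semi-supervised instance by
## enumerating every (z, o) configuration of the unknown proteins under the
## collapsed model (Dirichlet-multinomial class counts over all proteins,
## Beta-Bernoulli outlier counts with markers fixed non-outlier, NIW
## marginal likelihoods of the non-outlier members of each class, outlier t
## density for o = 1 proteins).
enumerate_tagm_posterior <- function(dataset, priors, outlier_spec) {
  x <- dataset$x
  k <- length(dataset$classes)
  unknown <- which(dataset$unknown)
  n_u <- length(unknown)
  stopifnot(n_u <= 6)
  marker_cls <- match(dataset$markers, dataset$classes)

  states <- expand.grid(rep(list(seq_len(2 * k)), n_u))  # per-protein state
  scores <- numeric(nrow(states))
  for (s in seq_len(nrow(states))) {
    st <- as.integer(states[s, ])
    z <- ((st - 1L) %% k) + 1L
    o <- as.integer(st > k)
    z_all <- marker_cls
    z_all[unknown] <- z
    o_all <- integer(nrow(x))
    o_all[unknown] <- o
    n_k <- tabulate(z_all, nbins = k)
    n_out <- sum(o_all)
    score <- sum(lgamma(priors$beta0 + n_k)) +
      lgamma(priors$u + n_out) + lgamma(priors$v + nrow(x) - n_out)
    for (j in seq_len(k)) {
      members <- which(z_all == j & o_all == 0L)
      score <- score + niw_marginal_loglik(x[members, , drop = FALSE], priors)
    }
    for (i in which(o_all == 1L))
      score <- score + mvt_loglik_direct(x[i, ], outlier_spec$location,
                                         outlier_spec$scale, outlier_spec$df)
    scores[s] <- score
  }
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  class_prob <- matrix(0, n_u, k)
  outlier_prob <- numeric(n_u)
  for (i in seq_len(n_u)) {
    st <- as.integer(states[, i])
    z <- ((st - 1L) %% k) + 1L
    o <- st > k
    for (j in seq_len(k)) class_prob[i, j] <- sum(w[z == j])
    outlier_prob[i] <- sum(w[o])
  }
  list(class_prob = class_prob, outlier_prob = outlier_prob)
}

## deterministic tiny two-class instance: 2 markers per class, 3 unknowns
tiny_instance <- function() {
  x <- rbind(c(0.0, 0.1), c(0.2, -0.1),     # class A markers
             c(3.0, 3.1), c(2.8, 3.0),      # class B markers
             c(0.1, 0.0),                   # near A
             c(2.9, 3.2),                   # near B
             c(1.5, 1.5))                   # ambiguous
  markers <- c("A", "A", "B", "B", "unknown", "unknown", "unknown")
  validate_dataset(x, markers,
                   protein_ids = paste0("pr", 1:7),
                   fraction_ids = c("f1", "f2"))
}

## hand-built chain container for the chain-operation tests
manual_chain <- function(alloc, outlier, outlier_prob, prob, ids, classes) {
  tagmix:::new_tagm_chain(alloc, outlier, outlier_prob, prob, ids, classes)
}

manual_chains <- function(chains, settings = list()) {
  tagmix:::new_tagm_chains(chains, settings)
}

## small helper: chains object with deterministic contents
make_toy_chains <- function(t_per_chain = c(3L, 3L), n_u = 2L, k = 3L,
                            seed = 42L) {
  set.seed(seed)
  chains <- lapply(seq_along(t_per_chain), function(cc) {
    t_c <- t_per_chain[cc]
    p <- array(0, c(n_u, k, t_c))
    for (tt in seq_len(t_c)) {
      raw <- matrix(rexp(n_u * k), n_u, k)
      p[, , tt] <- raw / rowSums(raw)
    }
    alloc <- matrix(sample(k, t_c * n_u, TRUE), t_c, n_u)
    outlier <- matrix(rbinom(t_c * n_u, 1L, 0.3), t_c, n_u)
    op <- matrix(runif(t_c * n_u), t_c, n_u)
    manual_chain(alloc, outlier, op, p, paste0("u", seq_len(n_u)),
                 paste0("C", seq_len(k)))
  })
  manual_chains(chains, settings = list(num_chains = length(chains)))
}
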