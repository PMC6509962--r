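# Fully Bayesian inference for the t-augmented Gaussian mixture.
#
# The sampler is collapsed: component means/covariances, mixture weights and
# the outlier weight are integrated out by conjugacy, so a sweep only
# resamples each unknown protein's class and outlier indicator from their
# joint 2K-state full conditional. The per-sweep class probabilities stored
# for each protein are the full-conditional masses marginalised over the
# outlier indicator (they sum to one over classes); the outlier probability
# is stored separately.

#' Sample the TAGM posterior with a collapsed Gibbs sampler
#'
#' Runs `num_chains` independent chains. Each chain starts from a
#' deterministic configuration (every unknown protein at its best class by
#' marker-informed posterior-predictive density, non-outlier) and uses its
#' own RNG stream derived from `seed`, so results are reproducible and
#' independent of whether chains run serially or concurrently. After
#' `burnin` sweeps are discarded, every `thin`-th sweep is retained:
#' `T = floor((num_iter - burnin) / thin)` samples per chain.
#'
#' @param dataset A `tagm_dataset`.
#' @param priors A `tagm_priors`; defaults to [default_priors()].
#' @param outlier_spec A `tagm_outlier`; defaults to [outlier_component()].
#' @param num_iter Total sweeps per chain.
#' @param burnin Initial sweeps discarded (`0 <= burnin < num_iter`).
#' @param thin Retain every `thin`-th post-burn-in sweep.
#' @param num_chains Number of independent chains.
#' @param seed Master seed from which per-chain seeds are derived.
#' @return A `tagm_chains` object: list of `tagm_chain` chains, the settings,
#'   and an empty `summary` slot (see [mcmc_process()]).
#' @examples
#' sim <- simulate_dataset(k = 3, d = 4, n = 120, seed = 1)
#' fit <- mcmc_train(sim$dataset, num_iter = 200, burnin = 50, thin = 5,
#'                   num_chains = 2, seed = 1)
#' fit
#' @export
mcmc_train <- function(dataset, priors = default_priors(dataset),
                       outlier_spec = outlier_component(dataset),
                       num_iter = 1000, burnin = 100, thin = 5,
                       num_chains = 4, seed = 1) {
  stopifnot(inherits(dataset, "tagm_dataset"))
  priors <- validate_priors(priors, ncol(dataset$x), length(dataset$classes))
  if (burnin < 0 || burnin >= num_iter)
    stop("'burnin' must satisfy 0 <= burnin < num_iter")
  if (thin < 1 || thin > num_iter - burnin)
    stop("'thin' must satisfy 1 <= thin <= num_iter - burnin")
  if (num_chains < 1) stop("'num_chains' must be at least 1")

  x <- dataset$x
  d <- ncol(x)
  k <- length(dataset$classes)
  unknown_idx <- which(dataset$unknown)
  if (length(unknown_idx) == 0L) stop("no unknown proteins to sample")
  marker_class <- match(dataset$markers, dataset$classes)  # NA for unknown
  marker_class[is.na(marker_class)] <- 0L

  ## deterministic start: best class by marker-informed predictive density;
  ## proteins fitting the outlier t better than every class start as
  ## outliers, so early class covariances are not corrupted by absorbed
  ## dispersed proteins (a slow-mixing mode of the sampler otherwise)
  pred <- matrix(0, length(unknown_idx), k)
  for (j in seq_len(k)) {
    y <- x[dataset$markers == dataset$classes[j], , drop = FALSE]
    st <- class_sufficient_stats(y, d)
    pred[, j] <- niw_predictive_logdensity(x[unknown_idx, , drop = FALSE],
                                           st, priors)
  }
  init_alloc <- max.col(pred, ties.method = "first")
  log_t <- dmvt_log(x[unknown_idx, , drop = FALSE], outlier_spec$location,
                    outlier_spec$scale, outlier_spec$df)
  init_outlier <- as.integer(log_t > pred[cbind(seq_along(init_alloc),
                                                init_alloc)])

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, num_chains)

  chains <- vector("list", num_chains)
  for (cc in seq_len(num_chains)) {
    set.seed(chain_seeds[cc])
    raw <- .collapsed_gibbs_chain(
      x, unknown_idx - 1L, as.integer(init_alloc - 1L), init_outlier,
      as.integer(marker_class - 1L),
      priors$mu0, priors$lambda0, priors$nu0, priors$S0, priors$beta0,
      priors$u, priors$v,
      outlier_spec$location, outlier_spec$scale, outlier_spec$df,
      as.integer(num_iter), as.integer(burnin), as.integer(thin))
    chains[[cc]] <- new_tagm_chain(
      alloc = raw$alloc, outlier = raw$outlier,
      outlier_prob = raw$outlier_prob, prob = raw$prob,
      protein_ids = rownames(x)[unknown_idx],
      classes = dataset$classes)
  }
  new_tagm_chains(chains,
                  settings = list(num_iter = num_iter, burnin = burnin,
                                  thin = thin, num_chains = num_chains,
                                  seed = seed, chain_seeds = chain_seeds))
}

## chain constructor shared by the sampler and the chain operations
new_tagm_chain <- function(alloc, outlier, outlier_prob, prob, protein_ids,
                           classes) {
  stopifnot(nrow(alloc) == nrow(outlier),
            nrow(alloc) == nrow(outlier_prob),
            dim(prob)[3] == nrow(alloc),
            dim(prob)[1] == ncol(alloc),
            dim(prob)[2] == length(classes),
            ncol(alloc) == length(protein_ids))
  structure(list(alloc = alloc, outlier = outlier,
                 outlier_prob = outlier_prob, prob = prob,
                 protein_ids = protein_ids, classes = classes),
            class = "tagm_chain")
}

new_tagm_chains <- function(chains, settings, summary = NULL) {
  ids <- chains[[1]]$protein_ids
  cls <- chains[[1]]$classes
  for (ch in chains)
    if (!identical(ch$protein_ids, ids) || !identical(ch$classes, cls))
      stop("chains are structurally inconsistent")
  structure(list(chains = chains, settings = settings, summary = summary),
            class = "tagm_chains")
}

#' Number of retained samples of a chain
#' @param chain A `tagm_chain`.
#' @export
chain_length <- function(chain) nrow(chain$alloc)

#' @export
print.tagm_chain <- function(x, ...) {
  cat("TAGM MCMC chain\n")
  cat("  Number of components:", length(x$classes), "\n")
  cat("  Number of proteins:", length(x$protein_ids), "\n")
  cat("  Number of iterations:", chain_length(x), "\n")
  invisible(x)
}

#' @export
print.tagm_chains <- function(x, ...) {
  cat("TAGM MCMC fit\n")
  cat("  Number of chains:", length(x$chains), "\n")
  cat("  Retained samples per chain:",
      paste(vapply(x$chains, chain_length, 0L), collapse = ", "), "\n")
  if (!is.null(x$summary)) cat("  Summary available\n")
  invisible(x)
}

#' @export
length.tagm_chains <- function(x) length(x$chains)

#' @export
`[[.tagm_chains` <- function(x, i) x$chains[[i]]

#' Shannon entropy of an allocation distribution (nats)
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`. Used for the
#' Monte-Carlo averaged per-protein uncertainty summaries; higher values
#' indicate more uncertain (possibly multi-localised) proteins.
#'
#' @param p Probability vector (must sum to 1 within 1e-6).
#' @return Entropy in nats, in `[0, log(length(p))]`.
#' @examples
#' shannon_entropy(rep(0.1, 10))  # log(10)
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) + 0  # + 0 avoids IEEE negative zero
}

.pooled_arrays <- function(params) {
  chains <- params$chains
  list(alloc = do.call(rbind, lapply(chains, `[[`, "alloc")),
       outlier = do.call(rbind, lapply(chains, `[[`, "outlier")),
       outlier_prob = do.call(rbind, lapply(chains, `[[`, "outlier_prob")),
       prob = .bind_cubes(lapply(chains, `[[`, "prob")))
}

.bind_cubes <- function(cubes) {
  dm <- dim(cubes[[1]])
  total <- sum(vapply(cubes, function(a) dim(a)[3], 0L))
  out <- array(0, c(dm[1], dm[2], total))
  at <- 0L
  for (a in cubes) {
    t_a <- dim(a)[3]
    if (t_a > 0) out[, , at + seq_len(t_a)] <- a
    at <- at + t_a
  }
  out
}

#' Summarise retained posterior samples
#'
#' Pools the retained samples of all chains (chains judged unconverged should
#' be removed first with [subset_chains()]) and computes, per unknown
#' protein: the posterior mean class-probability vector (`joint`), the modal
#' allocation and its probability, the equi-tailed 95% credible interval of
#' the allocated class's per-sample probability, the mean outlier indicator,
#' and the Monte-Carlo averaged Shannon entropy of the per-sample class
#' probabilities.
#'
#' @param params A `tagm_chains` object with at least one chain.
#' @return The same object with the `summary` slot populated: a data frame
#'   (`probabilities`) and the K-column `joint` matrix.
#' @export
mcmc_process <- function(params) {
  stopifnot(inherits(params, "tagm_chains"))
  if (length(params$chains) == 0L) stop("no chains to process")
  if (any(vapply(params$chains, chain_length, 0L) == 0L))
    stop("empty chains cannot be processed")
  pooled <- .pooled_arrays(params)
  ids <- params$chains[[1]]$protein_ids
  classes <- params$chains[[1]]$classes
  n_u <- length(ids)
  t_tot <- nrow(pooled$alloc)

  k <- length(classes)
  joint <- matrix(0, n_u, k, dimnames = list(ids, classes))
  lower <- upper <- shannon <- numeric(n_u)
  for (j in seq_len(n_u))
    joint[j, ] <- rowMeans(matrix(pooled$prob[j, , ], nrow = k))
  alloc <- max.col(joint, ties.method = "first")
  prob <- joint[cbind(seq_len(n_u), alloc)]
  for (j in seq_len(n_u)) {
    pj <- matrix(pooled$prob[j, , ], nrow = k)  # K x T
    qs <- stats::quantile(pj[alloc[j], ], c(0.025, 0.975), names = FALSE,
                          type = 7)
    lower[j] <- qs[1]
    upper[j] <- qs[2]
    pl <- ifelse(pj > 0, pj * log(pj), 0)
    shannon[j] <- mean(-colSums(pl))
  }
  summary_df <- data.frame(
    `tagm.mcmc.allocation` = classes[alloc],
    `tagm.mcmc.probability` = prob,
    `tagm.mcmc.probability.lowerquantile` = lower,
    `tagm.mcmc.probability.upperquantile` = upper,
    `tagm.mcmc.mean.shannon` = shannon,
    `tagm.mcmc.outlier` = colMeans(pooled$outlier),
    row.names = ids, check.names = FALSE)
  params$summary <- list(probabilities = summary_df, joint = joint,
                         pooled_samples = t_tot)
  params
}

#' Append posterior localisation summaries to the protein table
#'
#' Combines the processed MCMC summaries with the dataset. Marker proteins
#' keep their annotation with probability one (they are fixed, not sampled);
#' unknown proteins receive the posterior summaries. With `prob_joint = TRUE`
#' one `tagm.mcmc.joint.<class>` column per class is added; the outlier
#' column is controlled by `prob_outlier`.
#'
#' @param dataset A `tagm_dataset`.
#' @param params A `tagm_chains` object; processed automatically if needed.
#' @param prob_joint Add the per-class posterior mean probabilities.
#' @param prob_outlier Include the outlier-probability column.
#' @return A data frame in input protein order.
#' @export
mcmc_predict <- function(dataset, params, prob_joint = FALSE,
                         prob_outlier = TRUE) {
  stopifnot(inherits(dataset, "tagm_dataset"), inherits(params, "tagm_chains"))
  if (is.null(params$summary)) params <- mcmc_process(params)
  ids <- params$chains[[1]]$protein_ids
  classes <- params$chains[[1]]$classes
  ds_unknown <- rownames(dataset$x)[dataset$unknown]
  if (!setequal(ids, ds_unknown) || !identical(classes, dataset$classes))
    stop("parameters were trained on a different protein set")

  n <- nrow(dataset$x)
  all_ids <- rownames(dataset$x)
  res <- data.frame(
    `tagm.mcmc.allocation` = character(n),
    `tagm.mcmc.probability` = numeric(n),
    `tagm.mcmc.probability.lowerquantile` = numeric(n),
    `tagm.mcmc.probability.upperquantile` = numeric(n),
    `tagm.mcmc.mean.shannon` = numeric(n),
    `tagm.mcmc.outlier` = numeric(n),
    row.names = all_ids, check.names = FALSE)
  s <- params$summary$probabilities[ids, ]
  at <- match(ids, all_ids)
  res[at, names(s)] <- s
  fixed <- which(!dataset$unknown)
  res$`tagm.mcmc.allocation`[fixed] <- dataset$markers[fixed]
  res$`tagm.mcmc.probability`[fixed] <- 1
  res$`tagm.mcmc.probability.lowerquantile`[fixed] <- 1
  res$`tagm.mcmc.probability.upperquantile`[fixed] <- 1
  res$`tagm.mcmc.mean.shannon`[fixed] <- 0
  res$`tagm.mcmc.outlier`[fixed] <- 0

  if (isTRUE(prob_joint)) {
    jm <- matrix(0, n, length(classes),
                 dimnames = list(all_ids,
                                 paste0("tagm.mcmc.joint.", classes)))
    jm[at, ] <- params$summary$joint[ids, ]
    jm[cbind(fixed, match(dataset$markers[fixed], classes))] <- 1
    res <- cbind(res, as.data.frame(jm, check.names = FALSE))
  }
  if (!isTRUE(prob_outlier)) res$`tagm.mcmc.outlier` <- NULL
  res
}

#' Pooled per-sample localisation probabilities of one protein
#'
#' Returns the full posterior draw of class-probability vectors for a single
#' unknown protein, pooled over chains: a `T_total` x K matrix suitable for
#' violin-style plots of the localisation distribution.
#'
#' @param params A `tagm_chains` object.
#' @param protein_id Identifier of an unknown protein.
#' @export
protein_posterior <- function(params, protein_id) {
  stopifnot(inherits(params, "tagm_chains"))
  ids <- params$chains[[1]]$protein_ids
  j <- match(protein_id, ids)
  if (is.na(j))
    stop("protein '", protein_id,
         "' is not among the sampled (unknown) proteins")
  pooled <- .bind_cubes(lapply(params$chains, `[[`, "prob"))
  out <- t(pooled[j, , , drop = TRUE])
  if (dim(pooled)[3] == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- params$chains[[1]]$classes
  out
}
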