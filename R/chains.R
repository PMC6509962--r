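# Post-hoc manipulation of multi-chain sample containers. Every operation
# that modifies the retained samples clears the summary slot: the workflow
# re-runs mcmc_process() after chain selection or pooling, and a stale
# summary is a correctness hazard.

.clear_summary <- function(params) {
  params$summary <- NULL
  params
}

#' Keep a subset of chains
#'
#' Typically used to discard chains judged unconverged by [gelman_rubin()]
#' or [geweke_test()] before pooling.
#'
#' @param params A `tagm_chains` object.
#' @param keep Indices of the chains to retain.
#' @return A `tagm_chains` object with the selected chains and no summary.
#' @export
subset_chains <- function(params, keep) {
  stopifnot(inherits(params, "tagm_chains"))
  keep <- as.integer(keep)
  if (length(keep) == 0L) stop("at least one chain must be kept")
  if (any(keep < 1L) || any(keep > length(params$chains)))
    stop("chain index out of range 1..", length(params$chains))
  settings <- params$settings
  settings$num_chains <- length(keep)
  settings$kept_chains <- keep
  new_tagm_chains(params$chains[keep], settings)
}

#' Discard initial retained samples from every chain
#'
#' Removes the first `n` retained samples of each chain, e.g. when a chain
#' reaches its stationary regime only after the originally specified
#' burn-in.
#'
#' @param params A `tagm_chains` object.
#' @param n Number of leading samples to drop (`0 <= n < T`).
#' @export
burn_chains <- function(params, n) {
  stopifnot(inherits(params, "tagm_chains"))
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be non-negative")
  for (t_c in vapply(params$chains, chain_length, 0L))
    if (n >= t_c) stop("'n' must be smaller than the chain length (", t_c, ")")
  if (n == 0L) return(.clear_summary(params))
  chains <- lapply(params$chains, function(ch) {
    idx <- (n + 1L):chain_length(ch)
    new_tagm_chain(ch$alloc[idx, , drop = FALSE],
                   ch$outlier[idx, , drop = FALSE],
                   ch$outlier_prob[idx, , drop = FALSE],
                   ch$prob[, , idx, drop = FALSE],
                   ch$protein_ids, ch$classes)
  })
  settings <- params$settings
  settings$extra_burnin <- sum(settings$extra_burnin, n)
  new_tagm_chains(chains, settings)
}

#' Thin the retained samples of every chain
#'
#' Keeps samples at positions `freq, 2*freq, ...`, reducing storage and
#' autocorrelation; the new length is `floor(T / freq)`.
#'
#' @param params A `tagm_chains` object.
#' @param freq Thinning frequency (`1 <= freq <= T`).
#' @export
thin_chains <- function(params, freq) {
  stopifnot(inherits(params, "tagm_chains"))
  freq <- as.integer(freq)
  if (freq < 1L) stop("'freq' must be at least 1")
  for (t_c in vapply(params$chains, chain_length, 0L))
    if (freq > t_c) stop("'freq' exceeds the chain length (", t_c, ")")
  if (freq == 1L) return(.clear_summary(params))
  chains <- lapply(params$chains, function(ch) {
    idx <- seq.int(freq, chain_length(ch), by = freq)
    new_tagm_chain(ch$alloc[idx, , drop = FALSE],
                   ch$outlier[idx, , drop = FALSE],
                   ch$outlier_prob[idx, , drop = FALSE],
                   ch$prob[, , idx, drop = FALSE],
                   ch$protein_ids, ch$classes)
  })
  settings <- params$settings
  settings$extra_thin <- prod(settings$extra_thin, freq)
  new_tagm_chains(chains, settings)
}

#' Pool all chains into a single longer chain
#'
#' Concatenates the retained samples of all (converged) chains in chain
#' order into one chain, which gives better posterior estimates than any
#' single chain. Content is preserved bit-exactly.
#'
#' @param params A `tagm_chains` object with structurally identical chains.
#' @export
pool_chains <- function(params) {
  stopifnot(inherits(params, "tagm_chains"))
  if (length(params$chains) == 0L) stop("no chains to pool")
  pooled <- .pooled_arrays(params)
  ch <- new_tagm_chain(pooled$alloc, pooled$outlier, pooled$outlier_prob,
                       pooled$prob, params$chains[[1]]$protein_ids,
                       params$chains[[1]]$classes)
  settings <- params$settings
  settings$pooled_from <- length(params$chains)
  settings$num_chains <- 1L
  new_tagm_chains(list(ch), settings)
}

new_tagm_series <- function(values, chain_id, statistic) {
  stopifnot(all(is.finite(values)))
  structure(list(values = as.numeric(values), chain_id = chain_id,
                 statistic = statistic),
            class = "tagm_series")
}

#' @export
print.tagm_series <- function(x, ...) {
  cat("Diagnostic series '", x$statistic, "' (chain ", x$chain_id, "): ",
      length(x$values), " samples\n", sep = "")
  invisible(x)
}

series_values <- function(s) {
  if (inherits(s, "tagm_series")) s$values else as.numeric(s)
}

.series_per_chain <- function(params, statistic, fn) {
  stopifnot(inherits(params, "tagm_chains"))
  if (length(params$chains) == 0L) stop("no chains")
  lapply(seq_along(params$chains), function(i)
    new_tagm_series(fn(params$chains[[i]]), i, statistic))
}

#' Per-iteration outlier counts
#'
#' For each chain, the number of unknown proteins flagged as outliers at
#' each retained sample -- the primary scalar summary used to monitor
#' convergence across chains.
#'
#' @param params A `tagm_chains` object.
#' @return A list of `tagm_series`, one per chain.
#' @export
outlier_count_series <- function(params)
  .series_per_chain(params, "outliers", function(ch) rowSums(ch$outlier))

#' Per-iteration mean component allocation
#'
#' Mean over unknown proteins of the numeric class index (classes in fixed
#' alphabetical order) at each retained sample.
#'
#' @param params A `tagm_chains` object.
#' @return A list of `tagm_series`, one per chain.
#' @export
mean_component_series <- function(params)
  .series_per_chain(params, "mean-component", function(ch) rowMeans(ch$alloc))

#' Per-iteration mean outlier probability
#'
#' Mean over unknown proteins of the stored full-conditional outlier
#' probability at each retained sample.
#'
#' @param params A `tagm_chains` object.
#' @return A list of `tagm_series`, one per chain.
#' @export
mean_outlier_prob_series <- function(params)
  .series_per_chain(params, "mean-outlier-prob",
                    function(ch) rowMeans(ch$outlier_prob))
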