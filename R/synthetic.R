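# Synthetic fractionation-profile generator with ground truth. The
# statistical structure mirrors what the model assumes about spatial
# proteomics data: K overlapping Gaussian niches in D-dimensional profile
# space, a minority of dispersed heavy-tailed outliers, and a labelled
# marker subset that is never outlying.

.rmvnorm <- function(n, mu, sigma) {
  z <- matrix(rnorm(n * length(mu)), n)
  sweep(z %*% chol(sigma), 2L, mu, `+`)
}

.rmvt <- function(n, mu, sigma, df) {
  g <- rchisq(n, df) / df
  .rmvnorm(n, rep(0, length(mu)), sigma) / sqrt(g) +
    rep(mu, each = n)
}

#' Simulate a fractionation-profile dataset with ground truth
#'
#' Class means are drawn at mutual distances of at least `separation`
#' standard-deviation units (the per-class covariances have unit-scale
#' diagonals, so `separation` is directly interpretable as cluster
#' separation in sd units). Class covariances are random diagonal-dominant
#' SPD matrices, giving mildly correlated, elliptical niches. Each protein
#' is independently an outlier with probability `outlier_frac`; outliers
#' keep a class label but are drawn from a wide multivariate t (df 4, scale
#' twice the mean class covariance) centred at the global mean. Per class,
#' `marker_frac * n / K` non-outlier proteins are labelled as markers; the
#' rest are `"unknown"`.
#'
#' @param k Number of classes (default 10).
#' @param d Number of fractions (default 8).
#' @param n Number of proteins (default 2000).
#' @param marker_frac Fraction of proteins labelled as markers.
#' @param outlier_frac Per-protein outlier probability (`< 0.5`).
#' @param separation Minimal distance between class means, in sd units.
#' @param min_markers Minimum markers required per class.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return A list with `dataset` (a `tagm_dataset`) and `truth` (a
#'   `tagm_truth`: `class_means`, `class_covariances`, `true_labels`,
#'   `outlier_flags`, `marker_mask`, `seed`).
#' @examples
#' sim <- simulate_dataset(k = 5, d = 8, n = 500, seed = 1)
#' table(sim$truth$true_labels, sim$dataset$markers != "unknown")
#' @export
simulate_dataset <- function(k = 10, d = 8, n = 2000, marker_frac = 0.2,
                             outlier_frac = 0.05, separation = 5,
                             min_markers = 2, seed = 1) {
  if (k < 2 || d < 2) stop("need k >= 2 and d >= 2")
  if (marker_frac <= 0 || marker_frac >= 1)
    stop("'marker_frac' must be in (0, 1)")
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stop("'outlier_frac' must be in [0, 0.5)")
  if (separation <= 0) stop("'separation' must be positive")
  set.seed(seed)

  covs <- array(0, c(d, d, k))
  for (j in seq_len(k)) {
    w <- matrix(rnorm(d * d, sd = 0.15), d)
    covs[, , j] <- diag(runif(d, 0.5, 1.5)) + crossprod(w)
  }

  ## rejection placement: resample a mean until it clears all others
  means <- matrix(0, k, d)
  means[1, ] <- rnorm(d, sd = separation / sqrt(2))
  for (j in seq.int(2L, k)) {
    repeat {
      cand <- rnorm(d, sd = max(separation, separation * sqrt(k) / 2))
      if (min(sqrt(colSums((t(means[seq_len(j - 1L), , drop = FALSE]) -
                              cand)^2))) >= separation) break
    }
    means[j, ] <- cand
  }

  true_labels <- sample(rep_len(seq_len(k), n))
  outlier_flags <- rbinom(n, 1L, outlier_frac) == 1L

  x <- matrix(0, n, d)
  for (j in seq_len(k)) {
    rows <- which(true_labels == j & !outlier_flags)
    if (length(rows))
      x[rows, ] <- .rmvnorm(length(rows), means[j, ], covs[, , j])
  }
  if (any(outlier_flags)) {
    out_scale <- 2 * apply(covs, c(1, 2), mean)
    x[outlier_flags, ] <- .rmvt(sum(outlier_flags), colMeans(means),
                                out_scale, df = 4)
  }

  classes <- sprintf("class_%02d", seq_len(k))
  markers <- rep("unknown", n)
  marker_mask <- logical(n)
  per_class <- max(min_markers, round(marker_frac * n / k))
  for (j in seq_len(k)) {
    pool <- which(true_labels == j & !outlier_flags)
    if (length(pool) < min_markers)
      stop("class ", classes[j], " has too few non-outlier proteins ",
           "to supply markers")
    take <- sample(pool, min(per_class, length(pool)))
    markers[take] <- classes[j]
    marker_mask[take] <- TRUE
  }

  ids <- sprintf("P%05d", seq_len(n))
  dataset <- validate_dataset(x, markers, protein_ids = ids,
                              fraction_ids = sprintf("F%02d", seq_len(d)))
  truth <- structure(list(class_means = means, class_covariances = covs,
                          true_labels = true_labels,
                          outlier_flags = outlier_flags,
                          marker_mask = marker_mask, classes = classes,
                          seed = seed),
                     class = "tagm_truth")
  list(dataset = dataset, truth = truth)
}

#' Score predicted localisations against simulation ground truth
#'
#' Allocation accuracy is computed over non-outlier unknown proteins;
#' outlier recall and precision use a 0.5 threshold on the predicted
#' outlier probability (over unknown proteins). When a Shannon-entropy
#' column is available the mean entropy is reported separately for
#' correctly and incorrectly allocated proteins -- uncertain allocations
#' should be the wrong ones.
#'
#' @param results A results data frame from [map_predict()] or
#'   [mcmc_predict()] (protein ids as row names).
#' @param truth A `tagm_truth` object.
#' @param dataset The `tagm_dataset` the results refer to.
#' @return A list with `allocation_accuracy`, `outlier_recall`,
#'   `outlier_precision`, `mean_entropy_correct`, `mean_entropy_incorrect`.
#' @export
score_against_truth <- function(results, truth, dataset) {
  stopifnot(inherits(truth, "tagm_truth"), inherits(dataset, "tagm_dataset"))
  ids <- rownames(dataset$x)
  if (!all(ids[dataset$unknown] %in% rownames(results)))
    stop("results do not cover all unknown proteins")
  alloc_col <- intersect(c("tagm.mcmc.allocation", "tagm.map.allocation"),
                         names(results))[1]
  out_col <- intersect(c("tagm.mcmc.outlier", "tagm.map.outlier"),
                       names(results))[1]
  if (is.na(alloc_col)) stop("no allocation column in results")
  res <- results[ids, , drop = FALSE]

  unknown <- dataset$unknown
  honest <- unknown & !truth$outlier_flags
  predicted <- match(res[[alloc_col]], truth$classes)
  correct <- predicted == truth$true_labels
  acc <- mean(correct[honest])

  recall <- precision <- NA_real_
  if (!is.na(out_col)) {
    called <- unknown & res[[out_col]] > 0.5
    true_out <- unknown & truth$outlier_flags
    recall <- if (sum(true_out)) sum(called & true_out) / sum(true_out)
              else NA_real_
    precision <- if (sum(called)) sum(called & true_out) / sum(called)
                 else NA_real_
  }
  ent_correct <- ent_incorrect <- NA_real_
  if ("tagm.mcmc.mean.shannon" %in% names(results)) {
    sh <- res[["tagm.mcmc.mean.shannon"]]
    if (any(honest & correct)) ent_correct <- mean(sh[honest & correct])
    if (any(honest & !correct)) ent_incorrect <- mean(sh[honest & !correct])
  }
  list(allocation_accuracy = acc, outlier_recall = recall,
       outlier_precision = precision, mean_entropy_correct = ent_correct,
       mean_entropy_incorrect = ent_incorrect)
}
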