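#' Assemble and validate a fractionation-profile dataset
#'
#' Bundles a protein-by-fraction abundance matrix with its marker annotation.
#' Each protein is either a marker for one of the K subcellular classes or
#' carries the sentinel label `"unknown"`. Classes are ordered alphabetically
#' throughout the package (allocation indices, prior alignment, output
#' columns).
#'
#' Row normalisation of the abundances is not required by the model and is
#' therefore not enforced; a note is emitted when rows deviate strongly from
#' a common sum, since most labelled quantitation workflows produce
#' row-normalised relative intensities.
#'
#' @param abundances Numeric n x D matrix (or data frame) of non-negative
#'   relative intensities; row names are used as protein identifiers if
#'   `protein_ids` is missing.
#' @param markers Character vector of length n: a class name or `"unknown"`.
#' @param protein_ids,fraction_ids Optional identifier vectors; default to the
#'   dimnames of `abundances` or generated labels.
#' @return An object of class `tagm_dataset` with elements `x` (the matrix,
#'   with dimnames), `markers`, `classes` (sorted class names) and
#'   `unknown` (logical mask).
#' @examples
#' x <- matrix(runif(15), 5, 3)
#' d <- validate_dataset(x, c("A", "A", "B", "B", "unknown"))
#' d$classes
#' @export
validate_dataset <- function(abundances, markers, protein_ids = NULL,
                             fraction_ids = NULL) {
  x <- as.matrix(abundances)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (is.null(protein_ids)) protein_ids <- rownames(x)
  if (is.null(protein_ids)) protein_ids <- paste0("protein", seq_len(n))
  if (is.null(fraction_ids)) fraction_ids <- colnames(x)
  if (is.null(fraction_ids)) fraction_ids <- paste0("fraction", seq_len(d))
  protein_ids <- as.character(protein_ids)
  fraction_ids <- as.character(fraction_ids)

  if (length(markers) != n)
    stop("'markers' must have one label per protein (", n, " expected, got ",
         length(markers), ")")
  markers <- as.character(markers)
  if (length(protein_ids) != n)
    stop("'protein_ids' must have length ", n)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein identifiers: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  bad <- !is.finite(x)
  if (any(bad)) {
    off <- protein_ids[unique(which(bad, arr.ind = TRUE)[, 1L])]
    stop("non-finite abundance values for protein(s): ",
         paste(head(off, 5L), collapse = ", "))
  }
  if (d < 2L) stop("at least two fractions are required")
  if (any(is.na(markers)) )
    stop("marker labels must not be missing; use \"unknown\"")

  classes <- sort(unique(markers[markers != "unknown"]))
  k <- length(classes)
  if (k < 2L)
    stop("at least two marker classes are required (found ", k, ")")
  if (n < k) stop("fewer proteins than classes")
  counts <- table(factor(markers[markers != "unknown"], levels = classes))
  if (any(counts == 0L))
    stop("class without marker proteins: ",
         paste(names(counts)[counts == 0L], collapse = ", "))

  dimnames(x) <- list(protein_ids, fraction_ids)
  structure(list(x = x, markers = markers, classes = classes,
                 unknown = markers == "unknown"),
            class = "tagm_dataset")
}

#' @export
print.tagm_dataset <- function(x, ...) {
  cat("TAGM dataset:", nrow(x$x), "proteins x", ncol(x$x), "fractions\n")
  cat("Classes (", length(x$classes), "):\n", sep = "")
  counts <- table(factor(x$markers[!x$unknown], levels = x$classes))
  for (cl in x$classes) cat("  ", cl, ": ", counts[[cl]], " markers\n", sep = "")
  cat("Unknown proteins:", sum(x$unknown), "\n")
  invisible(x)
}

#' Default conjugate priors for the mixture
#'
#' Computes the weakly-informative defaults for the normal-inverse-Wishart,
#' Dirichlet and Beta hyperparameters. The prior mean `mu0` is the column
#' mean of the data; `lambda0 = 0.01` propagates covariance uncertainty into
#' the mean; `nu0 = D + 2` is the smallest integer degrees of freedom giving
#' a finite prior covariance; the scale matrix is the diagonal of the
#' per-column population variance deflated by `K^(1/D)`,
#' `S0 = diag((1/n) sum (X - Xbar)^2) / K^(1/D)`, a diffuse prior on the
#' niche covariances. The Dirichlet concentration is 1 per class and the
#' Beta(u = 2, v = 10) prior on the outlier weight encodes the belief that
#' roughly one protein in six may be an outlier a priori.
#'
#' @param dataset A `tagm_dataset`.
#' @return An object of class `tagm_priors` with elements `mu0`, `lambda0`,
#'   `nu0`, `S0`, `beta0`, `u`, `v`.
#' @export
default_priors <- function(dataset) {
  stopifnot(inherits(dataset, "tagm_dataset"))
  x <- dataset$x
  n <- nrow(x)
  d <- ncol(x)
  k <- length(dataset$classes)
  xbar <- colMeans(x)
  pop_var <- colSums((x - rep(xbar, each = n))^2) / n
  priors <- list(mu0 = xbar,
                 lambda0 = 0.01,
                 nu0 = d + 2,
                 S0 = diag(pop_var, d) / k^(1 / d),
                 beta0 = rep(1, k),
                 u = 2,
                 v = 10)
  class(priors) <- "tagm_priors"
  validate_priors(priors, d, k)
}

validate_priors <- function(priors, d, k) {
  stopifnot(is.list(priors))
  if (length(priors$mu0) != d) stop("mu0 must have length D = ", d)
  if (priors$lambda0 <= 0) stop("lambda0 must be positive")
  if (priors$nu0 <= d - 1) stop("nu0 must exceed D - 1")
  if (!isTRUE(all.equal(priors$S0, t(priors$S0))))
    stop("S0 must be symmetric")
  if (length(priors$beta0) != k) stop("beta0 must have length K = ", k)
  if (any(priors$beta0 <= 0)) stop("beta0 entries must be positive")
  if (priors$u <= 0 || priors$v <= 0) stop("u and v must be positive")
  class(priors) <- "tagm_priors"
  priors
}

#' Outlier-component specification
#'
#' The dispersed-protein component is a multivariate t centred at the global
#' data mean with scale equal to half the global empirical covariance and 4
#' degrees of freedom by default. These values are deliberately exposed:
#' the heavy-tailed component is a modelling device, and alternatives can be
#' supplied.
#'
#' @param dataset A `tagm_dataset`.
#' @param scale_factor Multiple of the global covariance used as scale.
#' @param df Degrees of freedom of the t density.
#' @return An object of class `tagm_outlier` with `location`, `scale`, `df`.
#' @export
outlier_component <- function(dataset, scale_factor = 0.5, df = 4) {
  stopifnot(inherits(dataset, "tagm_dataset"))
  if (df <= 0) stop("df must be positive")
  if (scale_factor <= 0) stop("scale_factor must be positive")
  scale <- regularize_covariance(scale_factor * stats::cov(dataset$x))
  structure(list(location = colMeans(dataset$x), scale = scale, df = df),
            class = "tagm_outlier")
}

#' Stabilise a covariance matrix
#'
#' Adds a small multiple of the identity, `c = epsilon_scale * mean(diag(S))`
#' (or `epsilon_scale` itself when the diagonal is all zero), repeatedly
#' escalating until a Cholesky factorisation succeeds. Well-conditioned input
#' is returned unchanged. When stabilisation was actually needed a warning is
#' emitted, mirroring standard practice for ill-conditioned profile
#' covariances arising from collinear fractions.
#'
#' @param s Symmetric matrix.
#' @param epsilon_scale Relative size of the identity multiple.
#' @param quiet Suppress the warning (internal callers).
#' @return A positive-definite matrix.
#' @export
regularize_covariance <- function(s, epsilon_scale = 1e-6, quiet = FALSE) {
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-8)))
    stop("covariance matrix must be symmetric")
  s <- (s + t(s)) / 2
  ok <- !inherits(try(chol(s), silent = TRUE), "try-error")
  if (ok) return(s)
  md <- mean(diag(s))
  c0 <- if (md > 0) epsilon_scale * md else epsilon_scale
  for (i in 0:30) {
    s_reg <- s + c0 * 10^i * diag(nrow(s))
    if (!inherits(try(chol(s_reg), silent = TRUE), "try-error")) {
      if (!quiet)
        warning("co-linearity detected; a small multiple of the identity ",
                "was added to the covariance", call. = FALSE)
      return(s_reg)
    }
  }
  stop("covariance could not be stabilised")
}

#' Principal-component projection of the profiles
#'
#' Deterministic PCA scores for a chosen pair of components, suitable for
#' external plotting of the organelle map. The sign convention is fixed by
#' making the largest-magnitude loading of each component positive.
#'
#' @param dataset A `tagm_dataset`.
#' @param dims Pair of distinct component indices within `1..D`.
#' @return An n x 2 matrix of scores with protein row names.
#' @export
project_pca <- function(dataset, dims = c(1, 2)) {
  stopifnot(inherits(dataset, "tagm_dataset"))
  d <- ncol(dataset$x)
  dims <- as.integer(dims)
  if (length(dims) != 2L || dims[1] == dims[2])
    stop("'dims' must be two distinct component indices")
  if (any(dims < 1L) || any(dims > d))
    stop("'dims' out of range 1..", d)
  pc <- stats::prcomp(dataset$x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2L, flip, `*`)
  scores[, dims, drop = FALSE]
}
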