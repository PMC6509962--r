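# Delimited-text input and output. The on-disk convention mirrors the
# feature-variable layout of curated spatial proteomics experiments: one row
# per protein, a protein-id first column, D numeric fraction columns, and a
# "markers" column using "unknown" as the sentinel label.

#' Read a fractionation-profile dataset from CSV/TSV
#'
#' The delimiter is auto-detected (comma or tab) unless given. The first
#' column is taken as the protein identifier; the marker column (default
#' `"markers"`) supplies the class labels; all remaining columns must be
#' numeric fraction intensities. The resolved dimensions and per-class
#' marker counts are reported at load.
#'
#' @param path Path to a delimited text file.
#' @param marker_column Name of the marker-annotation column.
#' @param sep Field separator; `NULL` for auto-detection.
#' @return A validated `tagm_dataset`.
#' @export
read_dataset <- function(path, marker_column = "markers", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = if (is.null(sep)) "auto" else sep,
                          header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  if (!marker_column %in% names(dt))
    stop("marker column '", marker_column, "' not found in ", path)
  ids <- as.character(dt[[1L]])
  markers <- as.character(dt[[marker_column]])
  frac <- dt[, setdiff(names(dt)[-1L], marker_column), drop = FALSE]
  for (cn in names(frac))
    if (!is.numeric(frac[[cn]])) {
      row <- which(is.na(suppressWarnings(as.numeric(frac[[cn]]))) |
                     !grepl("^[-0-9.eE+]*$", as.character(frac[[cn]])))[1L]
      stop("non-numeric value in fraction column '", cn, "', row ",
           if (is.na(row)) "?" else row)
    }
  ds <- validate_dataset(as.matrix(frac), markers, protein_ids = ids,
                         fraction_ids = names(frac))
  counts <- table(factor(ds$markers[!ds$unknown], levels = ds$classes))
  message("loaded ", nrow(ds$x), " proteins x ", ncol(ds$x), " fractions; ",
          length(ds$classes), " classes (markers: ",
          paste(names(counts), counts, sep = "=", collapse = ", "),
          "); ", sum(ds$unknown), " unknown")
  rs <- rowSums(ds$x)
  if (max(rs) > 0 && (max(rs) - min(rs)) > 0.25 * stats::median(rs))
    message("note: abundance rows are not uniformly normalised; ",
            "the model does not require row normalisation")
  ds
}

#' Write a per-protein results table as TSV
#'
#' Column names (including class names embedded in `tagm.mcmc.joint.*`
#' columns) are written verbatim; numeric values are written with 17
#' significant digits so that re-reading reproduces them bit-exactly.
#'
#' @param table A results data frame (row names are protein ids).
#' @param path Output path.
#' @param id_column Name for the protein-id column prepended from the row
#'   names.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path, id_column = "protein") {
  out <- table
  for (cn in names(out))
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  out <- cbind(stats::setNames(data.frame(rownames(table),
                                          stringsAsFactors = FALSE),
                               id_column),
               out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @param id_column Name of the protein-id column.
#' @return A data frame with protein ids as row names.
#' @export
read_results <- function(path, id_column = "protein") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  rownames(dt) <- dt[[id_column]]
  dt[[id_column]] <- NULL
  dt
}

#' Write a simulated dataset (and optionally its truth) to CSV
#'
#' @param sim Output of [simulate_dataset()].
#' @param path Destination CSV for the profiles + markers.
#' @param truth_path Optional destination CSV for the ground truth.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(sim, path, truth_path = NULL) {
  ds <- if (inherits(sim, "tagm_dataset")) sim else sim$dataset
  df <- data.frame(protein = rownames(ds$x), ds$x, markers = ds$markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(truth_path) && !inherits(sim, "tagm_dataset")) {
    tr <- sim$truth
    tdf <- data.frame(protein = rownames(ds$x),
                      true_class = tr$classes[tr$true_labels],
                      outlier = as.integer(tr$outlier_flags),
                      marker = as.integer(tr$marker_mask))
    utils::write.table(tdf, truth_path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Load prior and outlier-component overrides from a config file
#'
#' Accepts YAML (when the `yaml` package is available) or flat
#' `key = value` text. Recognised keys: `lambda0`, `nu0`, `u`, `v`,
#' `beta0` (scalar, recycled), `outlier_df`, `outlier_scale_factor`.
#'
#' @param path Path to the configuration file.
#' @return A named list of overrides.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  cfg <- NULL
  if (grepl("[.]ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    cfg <- yaml::yaml.load(paste(txt, collapse = "\n"))
  if (is.null(cfg)) {
    txt <- txt[nzchar(trimws(txt)) & !grepl("^\\s*#", txt)]
    parts <- strsplit(txt, "[=:]")
    cfg <- stats::setNames(
      lapply(parts, function(p) {
        val <- trimws(paste(p[-1L], collapse = ":"))
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) val else num
      }),
      vapply(parts, function(p) trimws(p[1L]), ""))
  }
  known <- c("lambda0", "nu0", "u", "v", "beta0", "outlier_df",
             "outlier_scale_factor")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[intersect(names(cfg), known)]
}

#' Apply configuration overrides to priors and outlier spec
#'
#' @param dataset A `tagm_dataset`.
#' @param config Named list from [read_config()] (or manual).
#' @return A list with `priors` and `outlier_spec`.
#' @export
apply_config <- function(dataset, config = list()) {
  priors <- default_priors(dataset)
  for (kk in intersect(names(config), c("lambda0", "nu0", "u", "v")))
    priors[[kk]] <- as.numeric(config[[kk]])
  if (!is.null(config$beta0))
    priors$beta0 <- rep(as.numeric(config$beta0),
                        length.out = length(dataset$classes))
  priors <- validate_priors(priors, ncol(dataset$x),
                            length(dataset$classes))
  spec <- outlier_component(
    dataset,
    scale_factor = if (is.null(config$outlier_scale_factor)) 0.5
                   else as.numeric(config$outlier_scale_factor),
    df = if (is.null(config$outlier_df)) 4 else as.numeric(config$outlier_df))
  list(priors = priors, outlier_spec = spec)
}

#' Save / load a multi-chain container
#'
#' Chains are serialised with R's native RDS format; the object layout
#' (grouped arrays `alloc`, `outlier`, `outlier_prob`, `prob` per chain plus
#' a `settings` list) is documented in the class constructor so third
#' parties can read it back.
#'
#' @param params A `tagm_chains` object.
#' @param path Destination file.
#' @return `path` (for `save_chains`) or the restored object.
#' @export
save_chains <- function(params, path) {
  stopifnot(inherits(params, "tagm_chains"))
  saveRDS(params, path)
  invisible(path)
}

#' @rdname save_chains
#' @export
load_chains <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "tagm_chains")) stop("not a chain container: ", path)
  obj
}
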