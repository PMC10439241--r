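#' Expression matrix with sample design and feature flags
#'
#' Container for a features-by-samples matrix of log2 intensities together
#' with the per-sample design (time point, plex/batch, channel for the TMT
#' arm; construct and replicate for the BioID arm), per-feature QC flags
#' (contaminant, reverse, only-identified-by-site) and keyword annotations.
#' All quantitative values are on the log2 scale; missing values are `NA`.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Log2 scale.
#' @param design data.frame with one row per sample (column `sample` matching
#'   `colnames(values)` plus arbitrary design columns such as
#'   `timepoint_days`, `plex`, `channel`, `construct`, `replicate`).
#' @param flags data.frame of logical QC flags with one row per feature;
#'   columns typically `contaminant`, `reverse`, `only_identified_by_site`.
#'   Defaults to all-`FALSE`.
#' @param annotations named list mapping feature ids to character vectors of
#'   keyword/term annotations. Defaults to empty.
#'
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, design, flags = NULL, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids in `values`")
  design <- as.data.frame(design)
  if (!"sample" %in% names(design))
    stop("`design` must contain a `sample` column")
  if (!setequal(design$sample, colnames(values)) ||
      nrow(design) != ncol(values))
    stop("`design` must describe exactly the samples in `values`")
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (is.null(flags)) {
    flags <- data.frame(
      contaminant = logical(nrow(values)),
      reverse = logical(nrow(values)),
      only_identified_by_site = logical(nrow(values))
    )
  }
  flags <- as.data.frame(flags)
  if (nrow(flags) != nrow(values))
    stop("`flags` must have one row per feature")
  if (!all(vapply(flags, is.logical, logical(1))))
    stop("all flag columns must be logical")
  rownames(flags) <- rownames(values)
  if (is.null(annotations)) annotations <- list()
  stopifnot(is.list(annotations))
  structure(
    list(values = values, design = design, flags = flags,
         annotations = annotations),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing values: %.1f%%\n", 100 * mean(is.na(x$values))))
  cat("  design columns:", paste(names(x$design), collapse = ", "), "\n")
  nflag <- vapply(x$flags, sum, integer(1))
  if (any(nflag > 0))
    cat("  flagged:", paste(sprintf("%s=%d", names(nflag)[nflag > 0],
                                    nflag[nflag > 0]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by features
#'
#' @param em an [expression_matrix()] object.
#' @param features character vector of feature ids or logical/integer index.
#' @return ExpressionMatrix restricted to the given features.
#' @export
subset_features <- function(em, features) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.character(features)) {
    missing_ids <- setdiff(features, rownames(em$values))
    if (length(missing_ids) > 0)
      stop("unknown feature ids: ", paste(utils::head(missing_ids, 5), collapse = ", "))
    idx <- match(features, rownames(em$values))
  } else idx <- features
  vals <- em$values[idx, , drop = FALSE]
  expression_matrix(vals, em$design, em$flags[idx, , drop = FALSE],
                    em$annotations[intersect(names(em$annotations), rownames(vals))])
}

# internal: accept a plain matrix or an ExpressionMatrix, return the matrix
.as_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a numeric matrix or an ExpressionMatrix")
}

# internal: put possibly modified values back into the original container
.restore_values <- function(x, values) {
  if (inherits(x, "ExpressionMatrix")) { x$values <- values; x } else values
}
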