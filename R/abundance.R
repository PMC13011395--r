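#' Construct an abundance matrix
#'
#' The central container of the package: a samples x features matrix of
#' relative abundances together with a logical presence mask and the
#' aggregation level. Each row sums to 1 (or 0 for an empty sample);
#' features flagged absent carry abundance 0.
#'
#' @param values numeric matrix, samples in rows, features in columns,
#'   with dimnames set to sample and feature identifiers.
#' @param presence logical matrix of the same shape; defaults to
#'   `values > 0`.
#' @param level one of `"votu"`, `"family"`, `"genus"`, `"species"`.
#' @param renormalize if `TRUE` (default), rows are rescaled to sum to 1
#'   after zeroing absent cells; all-zero rows are left at 0.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, presence = NULL,
                             level = c("votu", "family", "genus", "species"),
                             renormalize = TRUE) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample (row) and feature (column) names",
         call. = FALSE)
  }
  if (any(values < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (is.null(presence)) presence <- values > 0
  stopifnot(is.logical(presence), all(dim(presence) == dim(values)))
  values[!presence] <- 0
  if (renormalize) {
    rs <- rowSums(values)
    nz <- rs > 0
    values[nz, ] <- values[nz, , drop = FALSE] / rs[nz]
  }
  structure(
    list(values = values, presence = presence, level = level),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix [%s level]: %d samples x %d features\n",
              x$level, nrow(x$values), ncol(x$values)))
  cat(sprintf("  mean presence rate: %.3f\n", mean(x$presence)))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

sample_ids <- function(m) rownames(m$values)
feature_ids <- function(m) colnames(m$values)

#' Subset an abundance matrix by samples and/or features
#'
#' Rows are never renormalized by subsetting samples; subsetting features
#' keeps raw values (renormalize explicitly if compositional closure over
#' the retained features is wanted).
#'
#' @param m an `abundance_matrix`
#' @param samples,features character or integer indices; `NULL` keeps all
#' @param renormalize rescale rows to sum 1 after feature subsetting
#' @return an `abundance_matrix`
#' @export
subset_abundance <- function(m, samples = NULL, features = NULL,
                             renormalize = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  samples <- samples %||% seq_len(nrow(m$values))
  features <- features %||% seq_len(ncol(m$values))
  abundance_matrix(m$values[samples, features, drop = FALSE],
                   m$presence[samples, features, drop = FALSE],
                   level = m$level, renormalize = renormalize)
}
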