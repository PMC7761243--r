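#' Construct an expression matrix
#'
#' The central data container: a samples-by-features matrix of (raw or
#' transformed) intensities together with a two-level group label per
#' sample and an optional continuous phenotype.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_ids character vector of unique feature identifiers.
#' @param group vector of length `nrow(values)` with exactly two distinct
#'   levels, each with at least 3 samples.
#' @param phenotype optional numeric vector of length `nrow(values)`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (matrix with sample/feature dimnames), `group` (factor with
#'   two levels) and `phenotype` (numeric or `NULL`).
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              feature_ids = colnames(values),
                              group, phenotype = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("intensity values must be numeric")
  }
  sample_ids <- trimws(as.character(sample_ids))
  feature_ids <- trimws(as.character(feature_ids))
  if (length(sample_ids) != nrow(values)) {
    stop("length of sample_ids (", length(sample_ids),
         ") does not match number of rows (", nrow(values), ")")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length of feature_ids (", length(feature_ids),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyNA(values)) {
    stop("missing intensity values are not supported; impute before import")
  }
  group <- factor(as.vector(group))
  if (length(group) != nrow(values)) {
    stop("group labels must match the number of samples")
  }
  if (nlevels(group) != 2) {
    stop("exactly 2 group levels are required, found ", nlevels(group),
         " (", paste(levels(group), collapse = ", "), ")")
  }
  if (any(table(group) < 3)) {
    stop("each group needs at least 3 samples")
  }
  if (!is.null(phenotype)) {
    phenotype <- as.numeric(phenotype)
    if (length(phenotype) != nrow(values)) {
      stop("phenotype must have one value per sample")
    }
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, group = group, phenotype = phenotype),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tab <- table(x$group)
  cat("ExpressionMatrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$phenotype)) cat("phenotype: present\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Split the value matrix by group level
#'
#' @param x an `ExpressionMatrix`.
#' @return Named list of two samples-by-features matrices, in group
#'   level order.
#' @export
split_by_group <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  lapply(setNames(levels(x$group), levels(x$group)),
         function(g) x$values[x$group == g, , drop = FALSE])
}
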