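#' Natural-log transform intensities
#'
#' @param x `ExpressionMatrix` or numeric matrix with strictly positive
#'   entries.
#' @return Same type as the input, with `log()` applied elementwise.
#' @export
log_transform <- function(x) {
  v <- value_matrix(x)
  if (any(v <= 0)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1, ]
    stop("nonpositive intensity at sample '",
         rownames(v)[idx[1]] %||% idx[1], "', feature '",
         colnames(v)[idx[2]] %||% idx[2],
         "': log transform requires positive values")
  }
  replace_values(x, log(v))
}

#' Autoscale features to zero mean and unit variance
#'
#' Standardizes every feature column to mean 0 and sample standard
#' deviation 1 (denominator `n - 1`).
#'
#' @param x `ExpressionMatrix` or numeric matrix.
#' @return Same type as the input.
#' @export
autoscale <- function(x) {
  v <- value_matrix(x)
  s <- apply(v, 2, sd)
  if (any(s == 0)) {
    stop("constant features cannot be autoscaled: ",
         paste(colnames(v)[s == 0], collapse = ", "))
  }
  v <- scale(v, center = TRUE, scale = s)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  replace_values(x, v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

value_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
}

replace_values <- function(x, v) {
  if (inherits(x, "ExpressionMatrix")) {
    x$values <- v
    x
  } else {
    v
  }
}

#' Correlation-profile distance between features
#'
#' For each pair of features (i, j), computes `1 - cor(r_i, r_j)` where
#' `r_i` is feature i's vector of Pearson correlations with all other
#' features, both profiles taken over the features excluding i and j
#' themselves (self-correlation entries are constant 1 and would dilute
#' the profile).  Intended for log-transformed, non-autoscaled data.
#'
#' @param x `ExpressionMatrix` or numeric matrix with at least 4 features.
#' @return Symmetric p-by-p matrix with zero diagonal and entries in
#'   `[0, 2]`.
#' @export
correlation_profile_distance <- function(x) {
  v <- value_matrix(x)
  p <- ncol(v)
  if (p < 4) {
    stop("correlation profiles need at least 4 features (got ", p, ")")
  }
  R <- cor(v)
  n <- p - 2
  su <- rowSums(R)
  q <- rowSums(R^2)
  # profile sums with entries i and j removed
  S <- outer(su - 1, rep(1, p)) - R           # S[i, j] = sum_m!=i,j R[i, m]
  Q <- outer(q - 1, rep(1, p)) - R^2
  Cr <- R %*% R - 2 * R                       # cross sums minus excluded terms
  num <- Cr - S * t(S) / n
  den2 <- (Q - S^2 / n) * t(Q - S^2 / n)
  den <- sqrt(pmax(den2, 0))
  corr <- ifelse(den > 1e-12, num / den, 0)
  corr <- pmin(pmax(corr, -1), 1)
  d <- 1 - corr
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(colnames(v), colnames(v))
  d
}

#' Aggregate redundant features
#'
#' Collapses groups of features into single aggregated features whose
#' per-sample value is the median intensity of the group's members.
#' Three modes:
#' \describe{
#'   \item{`data_driven`}{complete-linkage hierarchical clustering on the
#'     [correlation_profile_distance()], cut at `tolerance`; all merged
#'     pairs are guaranteed a profile distance at most `tolerance`.}
#'   \item{`knowledge_driven`}{features sharing a class label in
#'     `grouping` are merged unconditionally; unlisted features stay
#'     singletons.}
#'   \item{`hybrid`}{data-driven merging applied within each class, so
#'     only chemically similar features with similar correlation profiles
#'     merge; never merges across classes.}
#' }
#' Works best on log-transformed, non-autoscaled data.
#'
#' @param x `ExpressionMatrix`.
#' @param mode one of `"none"`, `"data_driven"`, `"knowledge_driven"`,
#'   `"hybrid"`.
#' @param tolerance profile-distance cutoff in `(0, 2]` (data-driven and
#'   hybrid modes).
#' @param grouping named character vector (feature id -> class label) as
#'   returned by [read_grouping_file()]; required for knowledge-driven
#'   and hybrid modes.
#' @return list with `data` (aggregated `ExpressionMatrix`) and `map`
#'   (named list: aggregated id -> character vector of member ids; the
#'   member sets partition the original features, singletons keep their
#'   original id).
#' @export
aggregate_features <- function(x, mode = c("none", "data_driven",
                                           "knowledge_driven", "hybrid"),
                               tolerance = 0.5, grouping = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "ExpressionMatrix"))
  feats <- colnames(x$values)
  if (mode %in% c("data_driven", "hybrid")) {
    if (!is.numeric(tolerance) || length(tolerance) != 1 ||
        tolerance <= 0 || tolerance > 2) {
      stop("tolerance must be a single value in (0, 2]")
    }
  }
  if (mode %in% c("knowledge_driven", "hybrid") && is.null(grouping)) {
    stop(mode, " aggregation requires a feature grouping map")
  }

  groups <- switch(mode,
    none = as.list(setNames(feats, feats)),
    data_driven = data_driven_groups(x, feats, tolerance),
    knowledge_driven = knowledge_groups(feats, grouping),
    hybrid = hybrid_groups(x, feats, tolerance, grouping)
  )
  collapse_groups(x, groups)
}

data_driven_groups <- function(x, feats, tolerance, subset = NULL) {
  d <- attr(x, "profile_distance")
  if (is.null(d)) d <- correlation_profile_distance(x)
  if (!is.null(subset)) d <- d[subset, subset, drop = FALSE]
  hc <- hclust(as.dist(d), method = "complete")
  cl <- cutree(hc, h = tolerance)
  split(names(cl), cl)
}

knowledge_groups <- function(feats, grouping) {
  cls <- grouping[feats]
  names(cls) <- feats
  cls[is.na(cls)] <- paste0(".singleton.", feats[is.na(cls)])
  split(feats, cls[feats])
}

hybrid_groups <- function(x, feats, tolerance, grouping) {
  kg <- knowledge_groups(feats, grouping)
  out <- list()
  nms <- character(0)
  for (cl in names(kg)) {
    members <- kg[[cl]]
    if (length(members) < 2) {
      out <- c(out, list(members))
      nms <- c(nms, cl)
    } else {
      sub <- data_driven_groups(x, members, tolerance, subset = members)
      out <- c(out, unname(sub))
      nms <- c(nms, rep(cl, length(sub)))
    }
  }
  names(out) <- nms
  out
}

# merge member sets into median-aggregated columns with stable naming:
# singletons keep the original id, knowledge classes use the class label,
# data-driven merges concatenate member ids
collapse_groups <- function(x, groups) {
  feats <- colnames(x$values)
  members_list <- unname(groups)
  nms <- names(groups) %||% rep("", length(groups))
  ids <- vapply(seq_along(members_list), function(i) {
    members <- members_list[[i]]
    if (length(members) == 1) return(members)
    nm <- nms[i]
    if (nzchar(nm) && !startsWith(nm, ".singleton.") &&
        !grepl("^[0-9]+$", nm)) {
      return(nm)
    }
    paste(sort(members), collapse = ";")
  }, character(1))
  # order aggregated features by first member appearance
  ord <- order(vapply(members_list, function(m) min(match(m, feats)), 1L))
  members_list <- members_list[ord]
  ids <- ids[ord]
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }
  v <- vapply(members_list, function(members) {
    if (length(members) == 1) {
      x$values[, members]
    } else {
      apply(x$values[, members, drop = FALSE], 1, median)
    }
  }, numeric(nrow(x$values)))
  colnames(v) <- ids
  em <- expression_matrix(v, sample_ids = rownames(x$values),
                          feature_ids = ids, group = x$group,
                          phenotype = x$phenotype)
  list(data = em, map = setNames(members_list, ids))
}

#' Scan aggregation tolerances
#'
#' Evaluates the effective feature count and the features-to-sample-size
#' ratio at a series of aggregation tolerance values, to guide the choice
#' of how much to aggregate.  The recommended tolerance (the smallest
#' scanned value bringing the feature count at or below the sample count,
#' if any) is attached as attribute `"recommended"`.
#'
#' @param x `ExpressionMatrix` (log-transformed, not autoscaled).
#' @param tolerances numeric vector of cutoffs in `(0, 2]`.
#' @param mode `"data_driven"` or `"hybrid"`.
#' @param grouping feature grouping map (hybrid mode).
#' @return data.frame with columns `tolerance`, `effective_feature_count`,
#'   `features_to_sample_ratio`, sorted by tolerance; the count is
#'   non-increasing in the tolerance.
#' @export
tolerance_scan <- function(x, tolerances, mode = c("data_driven", "hybrid"),
                           grouping = NULL) {
  mode <- match.arg(mode)
  if (length(tolerances) == 0) stop("tolerance list must not be empty")
  tolerances <- sort(as.numeric(tolerances))
  # cache the profile distance so repeated cuts reuse one tree
  attr(x, "profile_distance") <- correlation_profile_distance(x)
  n <- nrow(x$values)
  counts <- vapply(tolerances, function(tol) {
    res <- aggregate_features(x, mode = mode, tolerance = tol,
                              grouping = grouping)
    ncol(res$data$values)
  }, 1L)
  out <- data.frame(tolerance = tolerances,
                    effective_feature_count = counts,
                    features_to_sample_ratio = counts / n)
  ok <- which(counts <= n)
  attr(out, "recommended") <- if (length(ok)) tolerances[min(ok)] else NA_real_
  out
}
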