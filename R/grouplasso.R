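#' Group-lasso design
#'
#' Bundles a continuous response, a feature matrix and a partition of
#' its columns into groups (typically subnetworks).  The response and
#' the feature columns are centered, so no intercept is fit.
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric response of length `nrow(X)`.
#' @param groups vector of length `ncol(X)` assigning each column to a
#'   group (factor, character or integer).
#' @param weights `"sqrt"` for the conventional `sqrt(p_l)` group
#'   weights, `"literal"` for weights `p_l`.
#' @return list of class `GroupDesign` with centered `X`, `y`, the group
#'   factor and per-group weights.
#' @export
group_design <- function(X, y, groups, weights = c("sqrt", "literal")) {
  weights <- match.arg(weights)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y must have one value per row of X")
  if (nrow(X) < 3) stop("at least 3 samples are required")
  if (length(groups) != ncol(X)) {
    stop("groups must assign every column of X")
  }
  if (all(y == 0)) stop("response vector is identically zero")
  groups <- factor(groups, levels = unique(groups))
  sizes <- as.integer(table(groups)[levels(groups)])
  w <- if (weights == "sqrt") sqrt(sizes) else as.numeric(sizes)
  structure(list(X = scale(X, center = TRUE, scale = FALSE),
                 y = y - mean(y), groups = groups,
                 sizes = sizes, w = w, weights = weights),
            class = "GroupDesign")
}

#' Regularization path for the group lasso
#'
#' `lambda_max = max_l ||X_l' y||_2 / (N w_l)` is the smallest penalty at
#' which all coefficients are zero; the path is `n_lambda` log-spaced
#' values from `lambda_max` down to `lambda_min_ratio * lambda_max`.
#'
#' @param design a [group_design()].
#' @param n_lambda path length.
#' @param lambda_min_ratio floor as a fraction of `lambda_max`.
#' @return strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(design, n_lambda = 100, lambda_min_ratio = 0.001) {
  stopifnot(inherits(design, "GroupDesign"))
  N <- nrow(design$X)
  lmax <- max(vapply(seq_along(levels(design$groups)), function(l) {
    cols <- design$groups == levels(design$groups)[l]
    sqrt(sum((crossprod(design$X[, cols, drop = FALSE],
                        design$y))^2)) / (N * design$w[l])
  }, numeric(1)))
  if (lmax <= 0) stop("response is uncorrelated with every feature")
  exp(seq(log(lmax), log(lambda_min_ratio * lmax),
          length.out = n_lambda))
}

#' Fit the group lasso at one penalty
#'
#' Minimizes `(1/(2N)) ||y - X beta||_2^2 + lambda sum_l w_l ||beta_l||_2`
#' by block coordinate descent (majorize-minimize group updates) to a
#' KKT tolerance of 1e-7.  Within-group coefficients are zero or nonzero
#' as a block; at `lambda = 0` the solution is least squares.
#'
#' @param design a [group_design()].
#' @param lambda nonnegative penalty.
#' @param beta0 optional warm start.
#' @param tol coordinate-update convergence tolerance.
#' @param maxit maximum number of sweeps.
#' @return numeric coefficient vector (one per column of `X`).
#' @export
fit_group_lasso <- function(design, lambda, beta0 = NULL, tol = 1e-9,
                            maxit = 10000L) {
  stopifnot(inherits(design, "GroupDesign"), lambda >= 0)
  grp <- as.integer(design$groups) - 1L
  beta0 <- beta0 %||% numeric(ncol(design$X))
  fit <- gl_fit_cpp(design$X, design$y, grp = grp, w = design$w,
                    lambda = lambda, beta = beta0, tol = tol,
                    maxit = as.integer(maxit))
  if (!fit$converged) {
    stop("group lasso did not converge in ", maxit,
         " sweeps (residual norm ", signif(sqrt(sum(fit$residual^2)), 4),
         ")")
  }
  as.numeric(fit$beta)
}

#' KKT residual of a group-lasso solution
#'
#' Independent subgradient check of optimality: for active groups the
#' norm of `-X_l' r / N + lambda w_l beta_l / ||beta_l||`, for inactive
#' groups the excess of `||X_l' r / N||` over `lambda w_l`.  The maximum
#' over groups is 0 at an exact solution.
#'
#' @param design a [group_design()].
#' @param beta coefficient vector.
#' @param lambda penalty used for the fit.
#' @return largest KKT violation across groups.
#' @export
kkt_residual <- function(design, beta, lambda) {
  stopifnot(inherits(design, "GroupDesign"))
  N <- nrow(design$X)
  r <- design$y - design$X %*% beta
  viol <- vapply(seq_along(levels(design$groups)), function(l) {
    cols <- design$groups == levels(design$groups)[l]
    g <- crossprod(design$X[, cols, drop = FALSE], r) / N
    b <- beta[cols]
    nb <- sqrt(sum(b^2))
    if (nb > 0) {
      sqrt(sum((g - lambda * design$w[l] * b / nb)^2))
    } else {
      max(0, sqrt(sum(g^2)) - lambda * design$w[l])
    }
  }, numeric(1))
  max(viol)
}

#' Rank subnetworks by phenotype association along the penalty path
#'
#' Stability-selected entry-order association: on each of `n_iterations`
#' subsamples (default 80% of samples without replacement) the full
#' regularization path is fit with warm starts and each group's entry
#' penalty (the largest path value at which its coefficient block is
#' nonzero) is recorded.  Groups are ranked by descending median entry
#' penalty; a group that never enters on a subsample contributes 0 for
#' that iteration.  Enrichment significance of the subnetworks is not an
#' input to this ranking.
#'
#' @param design a [group_design()].
#' @param n_iterations number of subsample iterations (at least 2).
#' @param subsample_frac fraction of samples per iteration.
#' @param n_lambda path length per fit.
#' @param lambda_min_ratio path floor as fraction of `lambda_max`.
#' @return data.frame of class `AssociationResult` with one row per
#'   group: `group`, `median_entry_lambda`, `entry_rank`,
#'   `stability_frequency` (fraction of iterations entering within the
#'   top quartile of the path) and `top_rank_frequency` (fraction of
#'   iterations entering first).
#' @export
association_ranking <- function(design, n_iterations = 500,
                                subsample_frac = 0.8, n_lambda = 100,
                                lambda_min_ratio = 0.001) {
  stopifnot(inherits(design, "GroupDesign"))
  if (n_iterations < 2) stop("n_iterations must be at least 2")
  N <- nrow(design$X)
  L <- nlevels(design$groups)
  m <- max(3L, floor(subsample_frac * N))
  entry <- matrix(NA_real_, n_iterations, L)
  entry_idx <- matrix(NA_integer_, n_iterations, L)
  grp_int <- as.integer(design$groups) - 1L

  for (it in seq_len(n_iterations)) {
    idx <- sample.int(N, m)
    Xs <- scale(design$X[idx, , drop = FALSE], center = TRUE,
                scale = FALSE)
    ys <- design$y[idx] - mean(design$y[idx])
    sub <- structure(list(X = Xs, y = ys, groups = design$groups,
                          sizes = design$sizes, w = design$w,
                          weights = design$weights),
                     class = "GroupDesign")
    path <- lambda_path(sub, n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio)
    beta <- numeric(ncol(Xs))
    ent <- rep(NA_integer_, L)
    for (li in seq_along(path)) {
      fit <- gl_fit_cpp(Xs, ys, grp = grp_int, w = design$w,
                        lambda = path[li], beta = beta, tol = 1e-7,
                        maxit = 10000L)
      beta <- as.numeric(fit$beta)
      active <- vapply(seq_len(L), function(l) {
        any(beta[design$groups == levels(design$groups)[l]] != 0)
      }, logical(1))
      newly <- which(active & is.na(ent))
      ent[newly] <- li
      if (!anyNA(ent)) break
    }
    entry_idx[it, ] <- ent
    entry[it, ] <- ifelse(is.na(ent), 0, path[ent])
  }

  med <- apply(entry, 2, median)
  top_quartile <- floor(n_lambda / 4)
  stab <- colMeans(!is.na(entry_idx) & entry_idx <= top_quartile)
  topfreq <- if (L == 1) {
    mean(entry[, 1] > 0)
  } else {
    colMeans(t(apply(entry, 1, function(e) e == max(e) & e > 0)))
  }
  out <- data.frame(group = levels(design$groups),
                    median_entry_lambda = med,
                    entry_rank = rank(-med, ties.method = "min"),
                    stability_frequency = stab,
                    top_rank_frequency = topfreq,
                    stringsAsFactors = FALSE)
  out <- out[order(out$entry_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AssociationResult", "data.frame")
  out
}
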