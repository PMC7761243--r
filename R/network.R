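#' Stability-selection configuration
#'
#' Bundles the tuning constants of the stability-selected joint network
#' estimator.  The defaults (`n_iterations = 500`, `tau = 0.9`,
#' `alpha = 1.3`, `beta = 0.9`) are the recommended operating point of
#' the balanced-subsampling procedure for imbalanced designs.
#'
#' @param n_iterations number of stability-selection iterations.
#' @param tau selection-probability threshold in `(0, 1]`; edges with
#'   selection probability above `tau` enter the final network.
#' @param alpha larger-group subsample multiplier (at least 1): the larger
#'   group contributes `round(alpha * n_min)` samples per iteration when
#'   subsampling is enabled.
#' @param beta smaller-group subsample fraction in `(0, 1]`: the smaller
#'   group contributes `round(beta * n_min)` distinct samples plus
#'   `round((1 - beta) * n_min)` resampled ones.
#' @param subsampling logical; enable balanced group subsampling.
#' @param lambda_grid optional descending positive grid for the penalty
#'   search; defaults to 20 log-spaced values from the empty-support
#'   `lambda_max` down to `0.01 * lambda_max`.
#' @param lambda optional fixed penalty; when `NULL` it is chosen by
#'   [select_lambda()] on the full data before iterating.
#' @param lambda_per_iteration logical; re-select the penalty on every
#'   subsample instead of once up front (slower).
#' @param mix elementwise penalty fraction of the joint estimator, as in
#'   [neighborhood_support()].
#' @param seed optional integer seed applied before iterating.
#' @return list of class `StabilityConfig`.
#' @export
stability_config <- function(n_iterations = 500, tau = 0.9, alpha = 1.3,
                             beta = 0.9, subsampling = FALSE,
                             lambda_grid = NULL, lambda = NULL,
                             lambda_per_iteration = FALSE, mix = 0.5,
                             seed = NULL) {
  if (n_iterations < 2) stop("n_iterations must be at least 2")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (alpha < 1) stop("alpha must be at least 1")
  if (beta <= 0 || beta > 1) stop("beta must be in (0, 1]")
  if (mix < 0 || mix >= 1) stop("mix must be in [0, 1)")
  structure(list(n_iterations = as.integer(n_iterations), tau = tau,
                 alpha = alpha, beta = beta, subsampling = subsampling,
                 lambda_grid = lambda_grid, lambda = lambda,
                 lambda_per_iteration = lambda_per_iteration, mix = mix,
                 seed = seed),
            class = "StabilityConfig")
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Balanced subsample of two sample groups
#'
#' Draws per-iteration index sets that equalize the effective group sizes
#' of an imbalanced design.  With `n_min` the size of the smaller group,
#' the larger group contributes `round(alpha * n_min)` distinct indices
#' (without replacement) and the smaller group `round(beta * n_min)`
#' distinct indices plus `round((1 - beta) * n_min)` indices drawn with
#' replacement from the whole smaller group.
#'
#' @param idx1,idx2 integer index vectors of the two groups.
#' @param alpha larger-group multiplier (`alpha * n_min` must not exceed
#'   the larger group's size).
#' @param beta smaller-group fraction in `(0, 1]`.
#' @return list with elements named as the inputs' order: `idx1` and
#'   `idx2` draws (the smaller group's draw may contain duplicates).
#' @export
balanced_subsample <- function(idx1, idx2, alpha = 1.3, beta = 0.9) {
  if (length(idx1) == 0 || length(idx2) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(idx1)
  n2 <- length(idx2)
  n_min <- min(n1, n2)
  n_max <- max(n1, n2)
  if (alpha * n_min > n_max) {
    stop("alpha * n_min (", alpha * n_min, ") exceeds the larger group (",
         n_max, ")")
  }
  small <- if (n1 <= n2) idx1 else idx2
  large <- if (n1 <= n2) idx2 else idx1
  large_draw <- sample(large, round_half_up(alpha * n_min), replace = FALSE)
  k_keep <- round_half_up(beta * n_min)
  k_add <- round_half_up((1 - beta) * n_min)
  small_draw <- sample(small, k_keep, replace = FALSE)
  if (k_add > 0) {
    small_draw <- c(small_draw, small[sample.int(length(small), k_add,
                                                 replace = TRUE)])
  }
  if (n1 <= n2) list(idx1 = small_draw, idx2 = large_draw)
  else list(idx1 = large_draw, idx2 = small_draw)
}

check_standardized <- function(x_by_group) {
  for (k in seq_along(x_by_group)) {
    s <- apply(x_by_group[[k]], 2, sd)
    if (any(abs(s - 1) > 1e-6)) {
      stop("columns of group ", k, " are not standardized ",
           "(sd deviates from 1 by more than 1e-6)")
    }
  }
  invisible(TRUE)
}

standardize_columns <- function(m) {
  m <- scale(m, center = TRUE, scale = apply(m, 2, sd))
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  m
}

#' Joint nodewise support estimation across two conditions
#'
#' For every feature j, regresses column j on all other columns in both
#' conditions simultaneously with a penalty that couples the two
#' conditions' coefficients of the same predictor: a Euclidean norm over
#' the condition pair (shared structure is selected jointly) combined
#' with an elementwise term (weight `mix`) that permits within-pair
#' sparsity, so an edge can be selected in one, both, or neither
#' condition.  Supports are symmetrized per condition with the AND rule
#' (an edge is kept only if selected from both endpoints).
#'
#' @param x_by_group list of two column-standardized matrices (same
#'   features, possibly different sample counts).
#' @param lambda positive penalty.
#' @param mix fraction of the penalty on the elementwise term, in
#'   `[0, 1)`; `0` gives the pure group penalty (edges then enter both
#'   conditions together).
#' @return list of two p-by-p binary symmetric support matrices.
#' @export
neighborhood_support <- function(x_by_group, lambda, mix = 0.5) {
  stopifnot(length(x_by_group) == 2, lambda > 0, mix >= 0, mix < 1)
  check_standardized(x_by_group)
  fit <- joint_nodewise_cpp(x_by_group[[1]], x_by_group[[2]],
                            lambdas = lambda, w = sqrt(2), mix = mix,
                            tol = 1e-6, maxit = 1000L)
  p <- ncol(x_by_group[[1]])
  s1 <- matrix(fit$support1[, , 1], p, p)
  s2 <- matrix(fit$support2[, , 1], p, p)
  dimnames(s1) <- dimnames(s2) <-
    list(colnames(x_by_group[[1]]), colnames(x_by_group[[1]]))
  list(s1, s2)
}

#' Default penalty grid for the joint estimator
#'
#' 20 log-spaced values from `lambda_max` (the smallest penalty giving
#' empty supports in both conditions) down to `0.01 * lambda_max`.
#'
#' @param x_by_group list of two column-standardized matrices.
#' @param n_lambda grid length.
#' @param mix elementwise penalty fraction, as in
#'   [neighborhood_support()].
#' @return descending numeric vector.
#' @export
default_lambda_grid <- function(x_by_group, n_lambda = 20, mix = 0.5) {
  check_standardized(x_by_group)
  X1 <- x_by_group[[1]]
  X2 <- x_by_group[[2]]
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  G1 <- crossprod(X1) / n1
  G2 <- crossprod(X2) / n2
  diag(G1) <- 0
  diag(G2) <- 0
  lam_max <- sgl_entry_lambda(abs(G1), abs(G2), mix = mix, w = sqrt(2))
  exp(seq(log(lam_max), log(0.01 * lam_max), length.out = n_lambda))
}

# smallest penalty zeroing every coefficient pair under the sparse-group
# prox: the largest root over pairs of ||soft(z, t*mix)||_2 = t*(1-mix)*w
sgl_entry_lambda <- function(A1, A2, mix, w) {
  g <- (1 - mix) * w
  a <- pmax(A1, A2)
  b <- pmin(A1, A2)
  crit <- function(ai, bi) {
    if (ai <= 0) return(0)
    if (mix == 0) return(sqrt(ai^2 + bi^2) / g)
    f <- function(t) {
      s1 <- max(ai - t * mix, 0)
      s2 <- max(bi - t * mix, 0)
      sqrt(s1^2 + s2^2) - t * g
    }
    hi <- ai / mix
    if (f(hi) > 0) return(hi)
    uniroot(f, c(1e-12, hi), tol = 1e-10)$root
  }
  # only the largest few pairs can attain the max; screen by upper bound
  ub <- sqrt(a^2 + b^2) / g + a / max(mix, 1e-12)
  cand <- which(ub >= max(ub) * 0.25)
  max(vapply(cand, function(i) crit(a[i], b[i]), numeric(1)))
}

#' Select the penalty by a BIC-type criterion
#'
#' Fits the joint nodewise regressions over the grid (warm-started,
#' descending) and returns the grid value minimizing
#' `sum_k sum_j [ n_k log(RSS_jk / n_k) + log(n_k) df_jk ]`.
#'
#' @param x_by_group list of two column-standardized matrices.
#' @param lambda_grid positive grid, sorted either way.
#' @param mix elementwise penalty fraction, as in
#'   [neighborhood_support()].
#' @return the selected penalty (deterministic given the input).
#' @export
select_lambda <- function(x_by_group, lambda_grid, mix = 0.5) {
  if (length(lambda_grid) == 0) stop("lambda grid must not be empty")
  check_standardized(x_by_group)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  if (length(lambda_grid) == 1) return(lambda_grid)
  fit <- joint_nodewise_cpp(x_by_group[[1]], x_by_group[[2]],
                            lambdas = lambda_grid, w = sqrt(2),
                            mix = mix, tol = 1e-6, maxit = 1000L)
  n1 <- nrow(x_by_group[[1]])
  n2 <- nrow(x_by_group[[2]])
  bic <- vapply(seq_along(lambda_grid), function(li) {
    sum(n1 * log(pmax(fit$rss1[, li], 1e-12) / n1) +
          log(n1) * fit$df1[, li]) +
      sum(n2 * log(pmax(fit$rss2[, li], 1e-12) / n2) +
            log(n2) * fit$df2[, li])
  }, numeric(1))
  lambda_grid[which.min(bic)]
}

#' Stability selection of the joint two-condition network
#'
#' Repeatedly subsamples both groups, runs [neighborhood_support()] on
#' each subsample (re-standardized), and records per condition the
#' fraction of iterations in which each edge was selected.  With
#' `config$subsampling = TRUE` the draws come from
#' [balanced_subsample()]; otherwise each group contributes 50% of its
#' samples without replacement.
#'
#' @param x_by_group list of two matrices (samples x features) on the
#'   autoscaled intensity scale; subsamples are re-standardized
#'   internally.
#' @param config a [stability_config()].
#' @return list with `P1`, `P2` (symmetric selection-probability matrices
#'   with zero diagonal) and `lambda` (the penalty used; a vector when
#'   re-selected per iteration).
#' @export
stability_select <- function(x_by_group, config = stability_config()) {
  stopifnot(length(x_by_group) == 2)
  if (!inherits(config, "StabilityConfig")) {
    stop("config must be created by stability_config()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  X1 <- as.matrix(x_by_group[[1]])
  X2 <- as.matrix(x_by_group[[2]])
  p <- ncol(X1)
  if (ncol(X2) != p) stop("both groups must share the feature set")

  std <- list(standardize_columns(X1), standardize_columns(X2))
  grid <- config$lambda_grid %||% default_lambda_grid(std,
                                                      mix = config$mix)
  lambda <- config$lambda
  if (is.null(lambda) && !config$lambda_per_iteration) {
    lambda <- select_lambda(std, grid, mix = config$mix)
  }

  P1 <- matrix(0, p, p)
  P2 <- matrix(0, p, p)
  lambdas_used <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    if (config$subsampling) {
      draw <- balanced_subsample(seq_len(nrow(X1)), seq_len(nrow(X2)),
                                 alpha = config$alpha, beta = config$beta)
    } else {
      draw <- list(idx1 = sample.int(nrow(X1), floor(nrow(X1) / 2)),
                   idx2 = sample.int(nrow(X2), floor(nrow(X2) / 2)))
    }
    sub <- list(standardize_columns(X1[draw$idx1, , drop = FALSE]),
                standardize_columns(X2[draw$idx2, , drop = FALSE]))
    lam_it <- if (config$lambda_per_iteration) {
      select_lambda(sub, grid, mix = config$mix)
    } else {
      lambda
    }
    lambdas_used <- c(lambdas_used, lam_it)
    supp <- neighborhood_support(sub, lam_it, mix = config$mix)
    P1 <- P1 + supp[[1]]
    P2 <- P2 + supp[[2]]
  }
  P1 <- P1 / config$n_iterations
  P2 <- P2 / config$n_iterations
  diag(P1) <- 0
  diag(P2) <- 0
  dimnames(P1) <- dimnames(P2) <- list(colnames(X1), colnames(X1))
  list(P1 = P1, P2 = P2,
       lambda = if (config$lambda_per_iteration) lambdas_used else lambda)
}

#' Partial correlations from a precision matrix
#'
#' The closed form `rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return partial-correlation matrix with unit diagonal replaced by 0.
#' @export
pcor_from_precision <- function(omega) {
  d <- diag(omega)
  if (any(d <= 0)) stop("precision matrix must have positive diagonal")
  r <- -omega / sqrt(outer(d, d))
  diag(r) <- 0
  r
}

#' Estimate partial correlations on a stability-selected support
#'
#' Keeps the edges with selection probability above `tau`, re-fits each
#' feature's neighborhood regression restricted to its selected
#' neighbors with per-predictor penalty factors `1 - P` (so
#' high-probability edges are nearly unpenalized; the selection
#' probabilities act as weights), assembles a sparse precision estimate
#' from the regression coefficients and residual variances, and converts
#' it to partial correlations via `-omega_ij / sqrt(omega_ii omega_jj)`.
#' Entries off the support are exactly zero.
#'
#' @param x_k samples-by-features matrix for one condition (autoscaled
#'   scale; standardized internally).
#' @param P_k selection-probability matrix for that condition.
#' @param tau threshold in `(0, 1]`.
#' @param lambda_refit base penalty of the refit (scaled by the penalty
#'   factors); near zero so that fully stable edges are fit by least
#'   squares.
#' @return symmetric partial-correlation matrix `R_k` with zero diagonal,
#'   support contained in `{P_k > tau}` and entries in `[-1, 1]`.
#' @export
estimate_partial_correlations <- function(x_k, P_k, tau = 0.9,
                                          lambda_refit = 1e-4) {
  x_k <- as.matrix(x_k)
  p <- ncol(x_k)
  n <- nrow(x_k)
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  supp <- P_k > tau
  diag(supp) <- FALSE
  supp <- supp & t(supp)  # P_k is symmetric; enforce it defensively
  R <- matrix(0, p, p, dimnames = list(colnames(x_k), colnames(x_k)))
  if (!any(supp)) return(R)
  deg <- rowSums(supp)
  if (any(deg >= n - 1)) {
    stop("support has nodes of degree >= n - 1 (",
         paste(head(which(deg >= n - 1)), collapse = ", "),
         "); the refit is unidentifiable")
  }
  xs <- standardize_columns(x_k)
  omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    nb <- which(supp[, j])
    if (length(nb) == 0) {
      omega[j, j] <- 1 / (sum(xs[, j]^2) / (n - 1))
      next
    }
    Xn <- xs[, nb, drop = FALSE]
    y <- xs[, j]
    pf <- 1 - P_k[nb, j]
    fit <- gl_fit_cpp(Xn, y, grp = seq_along(nb) - 1L, w = pf,
                      lambda = lambda_refit, beta = numeric(length(nb)),
                      tol = 1e-10, maxit = 10000L)
    beta <- as.numeric(fit$beta)
    rss <- sum(fit$residual^2)
    s2 <- rss / (n - 1)
    omega[j, j] <- 1 / s2
    omega[nb, j] <- -beta / s2
  }
  omega <- (omega + t(omega)) / 2
  Rfull <- pcor_from_precision(omega)
  R[supp] <- Rfull[supp]
  R[R > 1] <- 1
  R[R < -1] <- -1
  R
}

#' Assemble a joint two-condition network
#'
#' @param P1,P2 selection-probability matrices from [stability_select()].
#' @param R1,R2 partial-correlation matrices from
#'   [estimate_partial_correlations()].
#' @param tau selection threshold used.
#' @return object of class `JointNetwork` with elements `nodes`, `P1`,
#'   `P2`, `R1`, `R2`, `tau`.
#' @export
joint_network <- function(P1, P2, R1, R2, tau = 0.9) {
  nodes <- colnames(P1) %||% paste0("V", seq_len(ncol(P1)))
  stopifnot(all(dim(P1) == dim(P2)), all(dim(P1) == dim(R1)),
            all(dim(P1) == dim(R2)))
  structure(list(nodes = nodes, P1 = P1, P2 = P2, R1 = R1, R2 = R2,
                 tau = tau),
            class = "JointNetwork")
}

#' @export
print.JointNetwork <- function(x, ...) {
  cat("JointNetwork: ", length(x$nodes), " nodes; edges at tau=", x$tau,
      ": group1=", sum(x$R1[upper.tri(x$R1)] != 0),
      ", group2=", sum(x$R2[upper.tri(x$R2)] != 0), "\n", sep = "")
  invisible(x)
}

#' Edge table of a joint network
#'
#' One row per edge present in either condition, with partial
#' correlations, selection probabilities and an edge class
#' (`group1-only`, `group2-only`, `both`).  `feature_a < feature_b`
#' lexicographically.
#'
#' @param net a [joint_network()].
#' @return data.frame in the `edgelist.csv` schema.
#' @export
edge_table <- function(net) {
  p <- length(net$nodes)
  idx <- which(upper.tri(net$R1) & (net$R1 != 0 | net$R2 != 0),
               arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      pcor_group1 = numeric(0), pcor_group2 = numeric(0),
                      sel_prob_group1 = numeric(0),
                      sel_prob_group2 = numeric(0),
                      edge_class = character(0),
                      stringsAsFactors = FALSE))
  }
  a <- net$nodes[idx[, 1]]
  b <- net$nodes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  r1 <- net$R1[idx]
  r2 <- net$R2[idx]
  cls <- ifelse(r1 != 0 & r2 != 0, "both",
                ifelse(r1 != 0, "group1-only", "group2-only"))
  out <- data.frame(feature_a = a, feature_b = b,
                    pcor_group1 = r1, pcor_group2 = r2,
                    sel_prob_group1 = net$P1[idx],
                    sel_prob_group2 = net$P2[idx],
                    edge_class = cls, stringsAsFactors = FALSE)
  out[order(out$feature_a, out$feature_b), , drop = FALSE]
}
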