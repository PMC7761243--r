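#' Influence matrix of a condition network
#'
#' Converts a partial-correlation matrix into the influence matrix of
#' the topology-aware enrichment model.  The undirected network is given
#' a directed acyclic orientation by a fixed node ordering (the input
#' feature order by default): `A` carries the edge weights from earlier
#' to later nodes (strictly lower triangular), and the influence matrix
#' is `(I - A)^{-1}`, i.e. every node accumulates the propagated effects
#' of its upstream neighbors.  If the symmetric weight matrix has
#' spectral radius at or above 1 it is first rescaled to
#' `(1 - eps) / spectral radius`.  Rows are scaled to unit Euclidean
#' norm; an empty network yields the identity.
#'
#' @param R_k symmetric partial-correlation matrix with zero diagonal.
#' @param eps spectral-radius margin used when rescaling.
#' @param order optional permutation of `1:p` fixing the orientation.
#' @return p-by-p influence matrix with unit-norm rows.
#' @export
influence_matrix <- function(R_k, eps = 0.05, order = NULL) {
  p <- nrow(R_k)
  if (!isTRUE(all.equal(R_k, t(R_k), tolerance = 1e-8))) {
    stop("partial-correlation matrix must be symmetric")
  }
  W <- R_k
  diag(W) <- 0
  if (any(W != 0)) {
    sr <- max(abs(eigen(W, symmetric = TRUE, only.values = TRUE)$values))
    if (sr >= 1) W <- W * (1 - eps) / sr
  }
  ord <- order %||% seq_len(p)
  Wo <- W[ord, ord]
  A <- Wo
  A[upper.tri(A, diag = TRUE)] <- 0
  L <- diag(p) - A
  Lambda_o <- tryCatch(solve(L), error = function(e) {
    stop("influence matrix is singular after rescaling: ",
         conditionMessage(e))
  })
  # undo the ordering
  inv <- integer(p)
  inv[ord] <- seq_len(p)
  Lambda <- Lambda_o[inv, inv]
  rn <- sqrt(rowSums(Lambda^2))
  Lambda <- Lambda / rn
  dimnames(Lambda) <- dimnames(R_k)
  Lambda
}

#' Topology-aware subnetwork enrichment test
#'
#' Fits, per condition k, the mixed linear model
#' `Y = Lambda_k beta_k + Lambda_k gamma + eps` with a random
#' per-sample effect `gamma ~ N(0, sigma_g^2 I)` and noise
#' `eps ~ N(0, sigma_e^2 I)`, the two variance components shared across
#' conditions and estimated by REML (profiled in the eigenbasis of
#' `Lambda_k Lambda_k'`).  For every subnetwork S it tests
#' `H0: l_S' Lambda_1 beta_1 = l_S' Lambda_2 beta_2` (the indicator of S
#' propagated through the influence matrices) with a Wald statistic and
#' Satterthwaite-approximated degrees of freedom, so both mean changes
#' and connectivity changes between the condition networks drive the
#' statistic.  When both influence matrices are the identity the test
#' reduces exactly to a classical two-sample contrast on subnetwork
#' means.  P-values are two-sided and adjusted across subnetworks by
#' Benjamini-Hochberg.
#'
#' @param y_by_group list of two samples-by-features matrices
#'   (standardized scale).
#' @param lambda_by_group list of two influence matrices from
#'   [influence_matrix()], one per condition.
#' @param partition a [consensus_cluster()] partition (or a list with a
#'   `members` list of node-name vectors).
#' @param net optional [joint_network()] used to annotate per-condition
#'   edge counts.
#' @return data.frame of class `EnrichmentTable` with columns
#'   `subnetwork`, `n_nodes`, `n_edges_group1`, `n_edges_group2`,
#'   `statistic`, `pvalue`, `adj_pvalue`.
#' @export
netgsa_test <- function(y_by_group, lambda_by_group, partition,
                        net = NULL) {
  stopifnot(length(y_by_group) == 2, length(lambda_by_group) == 2)
  Y1 <- as.matrix(y_by_group[[1]])
  Y2 <- as.matrix(y_by_group[[2]])
  if (nrow(Y1) < 2 || nrow(Y2) < 2) {
    stop("at least 2 samples per condition are required")
  }
  p <- ncol(Y1)
  nodes <- colnames(Y1) %||% paste0("V", seq_len(p))
  members <- partition$members
  sizes <- vapply(members, length, 1L)
  if (any(sizes < 2)) {
    warning("skipping subnetworks of size < 2: ",
            paste(names(members)[sizes < 2], collapse = ", "))
    members <- members[sizes >= 2]
  }
  vc <- reml_variance_components(list(Y1, Y2), lambda_by_group)

  rows <- lapply(names(members), function(id) {
    nb <- members[[id]]
    l <- as.numeric(nodes %in% nb)
    tst <- wald_contrast(l, list(Y1, Y2), lambda_by_group, vc)
    ne1 <- ne2 <- NA_integer_
    if (!is.null(net)) {
      sub <- which(nodes %in% nb)
      ne1 <- sum(net$R1[sub, sub][upper.tri(net$R1[sub, sub])] != 0)
      ne2 <- sum(net$R2[sub, sub][upper.tri(net$R2[sub, sub])] != 0)
    }
    data.frame(subnetwork = id, n_nodes = length(nb),
               n_edges_group1 = ne1, n_edges_group2 = ne2,
               statistic = tst$statistic, pvalue = tst$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subnetwork = character(0), n_nodes = integer(0),
                      n_edges_group1 = integer(0),
                      n_edges_group2 = integer(0), statistic = numeric(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE)
  }
  out$adj_pvalue <- bh_adjust(out$pvalue)
  class(out) <- c("EnrichmentTable", "data.frame")
  attr(out, "variance_components") <- vc[c("sigma_g2", "sigma_e2")]
  out
}

# REML estimation of (sigma_g^2, sigma_e^2) shared across conditions.
# Var(Y_i | condition k) = sigma_g^2 Lambda_k Lambda_k' + sigma_e^2 I;
# in the eigenbasis Lambda_k Lambda_k' = U_k D_k U_k' the covariance is
# diagonal, so the profiled REML deviance is a cheap sum over
# eigendirections.
reml_variance_components <- function(y_by_group, lambda_by_group) {
  K <- length(y_by_group)
  d <- vector("list", K)
  t2 <- vector("list", K)
  nk <- integer(K)
  for (k in seq_len(K)) {
    Y <- y_by_group[[k]]
    nk[k] <- nrow(Y)
    M <- tcrossprod(lambda_by_group[[k]])
    e <- eigen(M, symmetric = TRUE)
    d[[k]] <- pmax(e$values, 0)
    Yc <- sweep(Y, 2, colMeans(Y))
    proj <- Yc %*% e$vectors
    t2[[k]] <- colSums(proj^2)
  }
  neg_reml <- function(par) {
    sg <- exp(par[1])
    se <- exp(par[2])
    val <- 0
    for (k in seq_len(K)) {
      v <- sg * d[[k]] + se
      val <- val + (nk[k] - 1) * sum(log(v)) + sum(t2[[k]] / v)
    }
    val
  }
  tot <- sum(unlist(t2)) / sum((nk - 1) * lengths(d))
  start <- log(c(tot / 2, tot / 2))
  fit <- optim(start, neg_reml, method = "L-BFGS-B",
               lower = log(1e-10), upper = log(1e6 * tot + 1))
  if (fit$convergence != 0) {
    # the profile can be a flat ridge (components unidentifiable, e.g.
    # both influence matrices identity); Nelder-Mead handles it
    fit <- optim(start, neg_reml, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  }
  if (fit$convergence != 0) {
    stop("variance-component optimization failed (code ",
         fit$convergence, "): ", fit$message %||% "")
  }
  sg <- exp(fit$par[1])
  se <- exp(fit$par[2])
  # Fisher information of (sigma_g^2, sigma_e^2) for the Satterthwaite df
  I11 <- I12 <- I22 <- 0
  for (k in seq_len(K)) {
    v <- sg * d[[k]] + se
    I11 <- I11 + 0.5 * (nk[k] - 1) * sum(d[[k]]^2 / v^2)
    I12 <- I12 + 0.5 * (nk[k] - 1) * sum(d[[k]] / v^2)
    I22 <- I22 + 0.5 * (nk[k] - 1) * sum(1 / v^2)
  }
  info <- matrix(c(I11, I12, I12, I22), 2, 2)
  list(sigma_g2 = sg, sigma_e2 = se, info = info, d = d, n = nk)
}

# Wald test of l'Lambda_1 beta_1 = l'Lambda_2 beta_2.  With the GLS
# estimator beta_k = Lambda_k^{-1} Ybar_k the contrast estimate is
# l'(Ybar_2 - Ybar_1) and its model variance sum_k l' V_k l / n_k with
# V_k = sigma_g^2 Lambda_k Lambda_k' + sigma_e^2 I.
wald_contrast <- function(l, y_by_group, lambda_by_group, vc) {
  ybar <- lapply(y_by_group, colMeans)
  est <- sum(l * ybar[[2]]) - sum(l * ybar[[1]])
  a_g <- 0
  a_e <- 0
  for (k in 1:2) {
    lam_l <- crossprod(lambda_by_group[[k]], l)
    a_g <- a_g + sum(lam_l^2) / vc$n[k]
    a_e <- a_e + sum(l^2) / vc$n[k]
  }
  v <- a_g * vc$sigma_g2 + a_e * vc$sigma_e2
  stat <- est / sqrt(v)
  df <- satterthwaite_df(c(a_g, a_e), c(vc$sigma_g2, vc$sigma_e2),
                         vc$info)
  pval <- 2 * pt(-abs(stat), df = df)
  list(statistic = stat, pvalue = pval, df = df)
}

satterthwaite_df <- function(a, sigma2, info) {
  v <- sum(a * sigma2)
  # Cov(sigma2-hat) ~ info^{-1}; use a pseudo-inverse when the two
  # components are unidentifiable (e.g. Lambda = I makes d constant)
  sv <- svd(info)
  pos <- sv$d > max(sv$d) * 1e-10
  cov <- sv$v[, pos, drop = FALSE] %*%
    diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  var_v <- drop(t(a) %*% cov %*% a)
  if (var_v <= 0) return(Inf)
  max(1, 2 * v^2 / var_v)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, clipped to
#' 1).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-feature differential statistics
#'
#' Welch two-sample t-test per feature with BH adjustment, plus the sign
#' of the mean difference (group 2 over group 1).  Used to build the
#' node table.
#'
#' @param x `ExpressionMatrix` on the preprocessed scale.
#' @param partition optional [consensus_cluster()] partition supplying
#'   subnetwork membership.
#' @return data.frame in the `nodelist.csv` schema.
#' @export
node_table <- function(x, partition = NULL) {
  v <- value_matrix(x)
  g <- x$group
  g1 <- levels(g)[1]
  res <- apply(v, 2, function(col) {
    a <- col[g == g1]
    b <- col[g != g1]
    tt <- t.test(b, a)
    c(direction = sign(mean(b) - mean(a)), pvalue = tt$p.value)
  })
  subnet <- rep("none", ncol(v))
  if (!is.null(partition)) {
    lab <- partition$labels[colnames(v)]
    subnet <- ifelse(is.na(lab) | lab == 0, "none", as.character(lab))
  }
  data.frame(feature_id = colnames(v),
             direction = res["direction", ],
             pvalue = res["pvalue", ],
             qvalue = bh_adjust(res["pvalue", ]),
             subnetwork = subnet,
             row.names = NULL, stringsAsFactors = FALSE)
}
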