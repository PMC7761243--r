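# Shared fixture builders and independent oracles.

# small valid intensity table on disk (6 samples, 3 features, 2 groups)
write_demo_csv <- function(path, sep = ",", transpose = FALSE) {
  values <- matrix(c(1.0, 2.0, 3.0,
                     1.5, 2.5, 3.5,
                     2.0, 3.0, 4.0,
                     4.0, 5.0, 6.0,
                     4.5, 5.5, 6.5,
                     5.0, 6.0, 7.0), nrow = 6, byrow = TRUE)
  samples <- paste0("s", 1:6)
  feats <- c("ala", "gly", "ser")
  group <- rep(c("A", "B"), each = 3)
  if (!transpose) {
    df <- data.frame(sample_id = samples, values, group = group)
    names(df) <- c("sample_id", feats, "group")
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    m <- rbind(t(values), group)
    df <- data.frame(feature = c(feats, "group"), m)
    names(df) <- c("feature", samples)
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# rank (Wilcoxon) AUC of scores against binary truth
rank_auc <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force Benjamini-Hochberg step-up, written directly from the
# definition as an independent oracle for bh_adjust()
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  adj
}

# draw n samples from the topology-aware enrichment generative model:
# Y_i = Lambda (beta + gamma_i) + eps_i
sample_netgsa_model <- function(n, Lambda, beta, sigma_g, sigma_e) {
  p <- nrow(Lambda)
  G <- matrix(rnorm(n * p, sd = sigma_g), n, p)
  E <- matrix(rnorm(n * p, sd = sigma_e), n, p)
  Y <- t(Lambda %*% (beta + t(G))) + E
  colnames(Y) <- rownames(Lambda) %||% paste0("V", seq_len(p))
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n draws whose sample mean is exactly 0 and sample covariance exactly
# Sigma (denominator n - 1), for closed-form agreement tests
exact_mvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  stopifnot(n > p)
  X0 <- matrix(rnorm(n * p), n, p)
  Xc <- scale(X0, center = TRUE, scale = FALSE)
  Z <- Xc %*% solve(chol(cov(Xc)))
  Z %*% chol(Sigma)
}

# hand-built chain precision matrix
chain_precision <- function(p, rho) {
  omega <- diag(p)
  for (i in seq_len(p - 1)) omega[i, i + 1] <- omega[i + 1, i] <- -rho
  omega
}

# chain partial-correlation matrix (edges rho on the chain)
chain_pcor <- function(p, rho) {
  R <- matrix(0, p, p)
  for (i in seq_len(p - 1)) R[i, i + 1] <- R[i + 1, i] <- rho
  R
}
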