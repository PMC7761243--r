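test_that("influence matrices have the documented closed forms", {
  # empty network: identity
  expect_equal(influence_matrix(matrix(0, 3, 3)), diag(3),
               ignore_attr = TRUE)

  # single edge rho = 0.5 on 2 nodes: (I - A)^{-1} row-normalized
  R <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  L <- influence_matrix(R)
  raw <- matrix(c(1, 0, 0.5, 1), 2, 2, byrow = TRUE)
  expect_equal(L, raw / sqrt(rowSums(raw^2)), ignore_attr = TRUE)

  # rows always unit norm; strong networks are rescaled, not rejected
  Rbig <- chain_pcor(6, 0.9)
  Lbig <- influence_matrix(Rbig)
  expect_equal(sqrt(rowSums(Lbig^2)), rep(1, 6), ignore_attr = TRUE)

  expect_error(influence_matrix(matrix(c(0, 1, 0, 0), 2, 2)),
               "symmetric")
})

test_that("with identity influence the test equals the classical contrast", {
  set.seed(21)
  p <- 8; n1 <- 25; n2 <- 30
  Y1 <- matrix(rnorm(n1 * p), n1, p)
  Y2 <- matrix(rnorm(n2 * p), n2, p)
  colnames(Y1) <- colnames(Y2) <- paste0("V", 1:p)
  part <- list(members = list(`1` = paste0("V", 1:4),
                              `2` = paste0("V", 5:8)))
  res <- netgsa_test(list(Y1, Y2), list(diag(p), diag(p)), part)

  pooled_s2 <- (sum(scale(Y1, scale = FALSE)^2) +
                  sum(scale(Y2, scale = FALSE)^2)) /
    (p * (n1 + n2 - 2))
  for (s in 1:2) {
    l <- as.numeric(paste0("V", 1:p) %in% part$members[[s]])
    classical <- (sum(l * colMeans(Y2)) - sum(l * colMeans(Y1))) /
      sqrt(pooled_s2 * sum(l) * (1 / n1 + 1 / n2))
    expect_equal(res$statistic[s], classical, tolerance = 1e-6)
  }
  expect_true(all(res$adj_pvalue >= res$pvalue))
})

test_that("a mean shift with no topology is detected at high power", {
  set.seed(22)
  p <- 10
  part <- list(members = list(`1` = paste0("V", 1:5),
                              `2` = paste0("V", 6:10)))
  rej <- replicate(60, {
    Y1 <- matrix(rnorm(50 * p), 50, p)
    Y2 <- matrix(rnorm(50 * p), 50, p)
    Y2[, 1:5] <- Y2[, 1:5] + 1  # 1 sd shift on subnetwork 1
    colnames(Y1) <- colnames(Y2) <- paste0("V", 1:p)
    res <- netgsa_test(list(Y1, Y2), list(diag(p), diag(p)), part)
    res$pvalue[res$subnetwork == "1"] < 0.05
  })
  expect_gte(mean(rej), 0.9)
})

test_that("permuted null data yields uniform p-values", {
  set.seed(23)
  p <- 8
  R <- chain_pcor(p, 0.4)
  Lam <- influence_matrix(R)
  part <- list(members = list(`1` = paste0("V", 1:4),
                              `2` = paste0("V", 5:8)))
  Y <- sample_netgsa_model(60, Lam, beta = rep(0.5, p), sigma_g = 0.6,
                           sigma_e = 1)
  pv <- replicate(200, {
    perm <- sample.int(60)
    res <- netgsa_test(list(Y[perm[1:30], ], Y[perm[31:60], ]),
                       list(Lam, Lam), part)
    res$pvalue
  })
  ks <- ks.test(as.numeric(pv), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("small subnetworks are skipped with a warning", {
  set.seed(24)
  p <- 6
  Y1 <- matrix(rnorm(20 * p), 20, p)
  Y2 <- matrix(rnorm(20 * p), 20, p)
  colnames(Y1) <- colnames(Y2) <- paste0("V", 1:p)
  part <- list(members = list(`1` = paste0("V", 1:5), `2` = "V6"))
  expect_warning(
    res <- netgsa_test(list(Y1, Y2), list(diag(p), diag(p)), part),
    "size < 2")
  expect_equal(res$subnetwork, "1")
})

test_that("BH adjustment matches hand computation and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(25)
  for (i in 1:50) {
    pv <- runif(sample(1:40, 1))
    adj <- bh_adjust(pv)
    expect_equal(adj, bh_brute_force(pv))
    expect_true(all(adj >= pv & adj <= 1))
  }
})

test_that("node statistics flag shifted features with correct signs", {
  set.seed(26)
  v <- matrix(exp(rnorm(40 * 4)), 40, 4)
  v[21:40, 1] <- v[21:40, 1] * exp(2)   # strong increase in group B
  v[21:40, 2] <- v[21:40, 2] * exp(-2)  # strong decrease
  em <- expression_matrix(v, paste0("s", 1:40), c("up", "dn", "n1", "n2"),
                          rep(c("A", "B"), each = 20))
  em <- autoscale(log_transform(em))
  nt <- node_table(em)
  expect_equal(nt$direction[1:2], c(1, -1))
  expect_lt(nt$qvalue[1], 0.05)
  expect_true(all(nt$qvalue >= nt$pvalue))
  expect_equal(nt$subnetwork, rep("none", 4))
})
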