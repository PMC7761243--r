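std_split <- function(sim) {
  em <- autoscale(log_transform(sim$data))
  split_by_group(em)
}
standardize <- function(m) scale(m, center = TRUE, scale = apply(m, 2, sd))

test_that("balanced subsampling draws the documented sizes", {
  set.seed(1)
  draw <- balanced_subsample(seq_len(100), 101:774, alpha = 1.3,
                             beta = 0.9)
  expect_length(draw$idx2, 130L)       # round(1.3 * 100)
  expect_length(draw$idx1, 100L)       # 90 distinct + 10 resampled
  expect_equal(anyDuplicated(draw$idx2), 0L)
  expect_gte(length(unique(draw$idx1)), 90L)
  expect_true(all(draw$idx1 %in% 1:100))
  expect_true(all(draw$idx2 %in% 101:774))

  # beta = 1: the whole smaller group, no resampling
  set.seed(2)
  d2 <- balanced_subsample(1:10, 11:60, alpha = 1.5, beta = 1)
  expect_setequal(d2$idx1, 1:10)

  # determinism under a fixed seed
  set.seed(3); a <- balanced_subsample(1:50, 51:500)
  set.seed(3); b <- balanced_subsample(1:50, 51:500)
  expect_identical(a, b)

  expect_error(balanced_subsample(1:10, 11:20, alpha = 1.3),
               "exceeds the larger group")
})

test_that("joint nodewise supports vanish at large penalties and recover strong edges", {
  set.seed(10)
  omega <- chain_precision(4, 0.45)
  sigma <- solve(omega)
  X1 <- standardize(MASS::mvrnorm(500, rep(0, 4), sigma))
  X2 <- standardize(MASS::mvrnorm(500, rep(0, 4), sigma))
  supp_hi <- neighborhood_support(list(X1, X2), lambda = 10)
  expect_equal(sum(supp_hi[[1]]), 0)
  expect_equal(sum(supp_hi[[2]]), 0)

  supp_lo <- neighborhood_support(list(X1, X2), lambda = 0.08)
  expect_equal(supp_lo[[1]][1, 2], 1)
  expect_equal(supp_lo[[2]][1, 2], 1)

  # non-standardized input is refused
  expect_error(neighborhood_support(list(X1 * 2, X2), lambda = 0.1),
               "not standardized")
})

test_that("differential edges are recovered in the correct condition", {
  set.seed(11)
  omega <- chain_precision(4, 0.45)
  hits <- replicate(50, {
    X1 <- standardize(MASS::mvrnorm(300, rep(0, 4), solve(omega)))
    X2 <- standardize(matrix(rnorm(300 * 4), 300, 4))
    supp <- neighborhood_support(list(X1, X2), lambda = 0.2)
    supp[[1]][1, 2] == 1 && supp[[2]][1, 2] == 0
  })
  expect_gte(mean(hits), 0.8)
})

test_that("the BIC rule picks sparse penalties on noise and the sole grid value when forced", {
  set.seed(12)
  X1 <- standardize(matrix(rnorm(120 * 10), 120, 10))
  X2 <- standardize(matrix(rnorm(120 * 10), 120, 10))
  expect_equal(select_lambda(list(X1, X2), lambda_grid = 0.3), 0.3)
  expect_error(select_lambda(list(X1, X2), numeric(0)), "empty")

  grid <- default_lambda_grid(list(X1, X2))
  expect_length(grid, 20L)
  expect_true(all(diff(grid) < 0))
  lam <- select_lambda(list(X1, X2), grid)
  supp <- neighborhood_support(list(X1, X2), lam)
  density <- sum(supp[[1]] + supp[[2]]) / (2 * 10 * 9)
  expect_lte(density, 0.05)
})

test_that("denser true graphs get smaller selected penalties on average", {
  set.seed(13)
  omega <- chain_precision(8, 0.4)
  lams <- replicate(10, {
    Xd1 <- standardize(MASS::mvrnorm(100, rep(0, 8), solve(omega)))
    Xd2 <- standardize(MASS::mvrnorm(100, rep(0, 8), solve(omega)))
    Xe1 <- standardize(matrix(rnorm(100 * 8), 100, 8))
    Xe2 <- standardize(matrix(rnorm(100 * 8), 100, 8))
    grid <- default_lambda_grid(list(Xd1, Xd2))
    c(dense = select_lambda(list(Xd1, Xd2), grid),
      empty = select_lambda(list(Xe1, Xe2), grid))
  })
  expect_lte(mean(lams["dense", ]), mean(lams["empty", ]))
})

test_that("stability selection separates true and null edges on a hub graph", {
  # star: node 1 connected to nodes 2..6, nodes 7..20 independent
  p <- 20
  omega <- diag(p)
  omega[1, 2:6] <- omega[2:6, 1] <- -0.3
  sigma <- solve(omega)
  set.seed(14)
  X1 <- MASS::mvrnorm(200, rep(0, p), sigma)
  X2 <- MASS::mvrnorm(200, rep(0, p), sigma)
  sel <- stability_select(list(X1, X2),
                          stability_config(n_iterations = 100, seed = 14))
  truth <- (omega != 0) * 1; diag(truth) <- 0
  ut <- upper.tri(truth)
  expect_gte(mean(sel$P1[ut][truth[ut] == 1]), 0.9)
  expect_lte(mean(sel$P1[ut][truth[ut] == 0]), 0.2)

  # symmetry, zero diagonal, determinism
  expect_equal(sel$P1, t(sel$P1))
  expect_equal(diag(sel$P2), rep(0, p), ignore_attr = TRUE)
  sel2 <- stability_select(list(X1, X2),
                           stability_config(n_iterations = 100, seed = 14))
  expect_identical(sel, sel2)
})

test_that("exchangeable groups get near-identical selection probabilities", {
  # identical generating distributions: at a moderate penalty, where
  # true edges are firmly selected and null pairs firmly rejected, the
  # estimator must treat the two groups symmetrically
  spec <- simulation_spec(p = 10, n1 = 400, n2 = 400,
                          block_sizes = c(5, 5),
                          within_block_pcor = 0.45, seed = 15)
  xg <- std_split(simulate_two_group(spec))
  sel <- stability_select(xg, stability_config(n_iterations = 300,
                                               lambda = 0.25,
                                               seed = 15))
  expect_lte(max(abs(sel$P1 - sel$P2)), 0.15)
})

test_that("partial correlations match the precision closed form exactly", {
  expect_equal(pcor_from_precision(matrix(c(2, -1, -1, 2), 2, 2))[1, 2],
               0.5)

  # data with exact sample moments + fully stable support => exact refit
  omega <- chain_precision(4, 0.4)
  omega[1, 4] <- omega[4, 1] <- -0.15
  set.seed(16)
  X <- exact_mvn(40, solve(omega))
  P <- (omega != 0) * 1; diag(P) <- 0
  R <- estimate_partial_correlations(X, P, tau = 0.9)
  expected <- pcor_from_precision(omega)
  expect_lt(max(abs(R - expected)), 1e-6)

  # empty support gives the zero matrix
  R0 <- estimate_partial_correlations(X, matrix(0, 4, 4), tau = 0.9)
  expect_equal(R0, matrix(0, 4, 4), ignore_attr = TRUE)
})

test_that("chain-graph partial correlations are recovered from data", {
  omega <- chain_precision(10, 0.4)
  set.seed(17)
  X <- MASS::mvrnorm(1000, rep(0, 10), solve(omega))
  P <- (omega != 0) * 0.99; diag(P) <- 0
  R <- estimate_partial_correlations(X, P, tau = 0.9)
  on_edges <- R[abs(pcor_from_precision(omega)) > 0]
  expect_lte(mean(abs(on_edges - 0.4)), 0.05)
  # support containment and symmetry
  expect_true(all(R[P <= 0.9] == 0))
  expect_equal(R, t(R))
  expect_true(all(abs(R) <= 1))

  # saturated support on too few samples is unidentifiable
  Psat <- matrix(1, 10, 10); diag(Psat) <- 0
  expect_error(estimate_partial_correlations(X[1:8, ], Psat, 0.9),
               "degree")
})

test_that("imbalanced designs lose spurious large-group edges under subsampling", {
  count_edges <- function(P, tau = 0.9) sum(P[upper.tri(P)] > tau)
  spec <- simulation_spec(p = 20, n1 = 60, n2 = 600,
                          block_sizes = c(10, 10),
                          within_block_pcor = 0.25, seed = 18)
  xg <- std_split(simulate_two_group(spec))
  no_ss <- stability_select(xg, stability_config(n_iterations = 60,
                                                 seed = 18))
  with_ss <- stability_select(xg, stability_config(n_iterations = 60,
                                                   subsampling = TRUE,
                                                   seed = 18))
  expect_lt(count_edges(with_ss$P2), count_edges(no_ss$P2))
})
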