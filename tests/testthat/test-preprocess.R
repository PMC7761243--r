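make_em <- function(values, groups = NULL) {
  n <- nrow(values)
  groups <- groups %||% rep(c("A", "B"), length.out = n)
  expression_matrix(values,
                    sample_ids = paste0("s", seq_len(n)),
                    feature_ids = colnames(values) %||%
                      paste0("f", seq_len(ncol(values))),
                    group = groups)
}

test_that("log transform is elementwise natural log with domain checks", {
  v <- matrix(c(exp(1), 1, 2, 4, 8, 16), 6, 3)[, 1, drop = FALSE]
  v <- cbind(v, v + 1, v + 2)
  em <- make_em(v)
  lt <- log_transform(em)
  expect_equal(lt$values[1, 1], 1.0)
  expect_equal(lt$values[2, 1], 0.0)
  expect_equal(lt$values, log(v), ignore_attr = TRUE)

  v[3, 2] <- 0
  expect_error(log_transform(make_em(v)), "nonpositive")
})

test_that("autoscaling gives exact zero mean and unit sample sd", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  colnames(v) <- c("x", "y")
  em <- expression_matrix(rbind(v, v + 0.5), paste0("s", 1:6),
                          c("x", "y"), rep(c("A", "B"), each = 3))
  sc <- autoscale(em)
  expect_lt(max(abs(colMeans(sc$values))), 1e-12)
  expect_lt(max(abs(apply(sc$values, 2, sd) - 1)), 1e-12)

  simple <- scale(matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.numeric(autoscale(matrix(c(1, 2, 3), 3, 1))),
               c(-1, 0, 1))

  const <- cbind(v, z = rep(2, 3))
  expect_error(autoscale(const), "constant features.*z")
})

test_that("correlation-profile distance has the closed-form limits", {
  set.seed(42)
  base <- matrix(rnorm(40 * 3), 40, 3)
  # duplicated feature pair plus independent fillers
  X <- cbind(a = base[, 1], b = base[, 1], c = base[, 2], d = base[, 3])
  d <- correlation_profile_distance(X)
  expect_equal(dim(d), c(4L, 4L))
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d["a", "b"], 0, tolerance = 1e-10)

  # a feature and its negation have exactly opposite profiles
  Xn <- cbind(a = base[, 1], neg = -base[, 1], c = base[, 2],
              d = base[, 3])
  dn <- correlation_profile_distance(Xn)
  expect_equal(dn["a", "neg"], 2, tolerance = 1e-10)

  expect_error(correlation_profile_distance(X[, 1:3]), "at least 4")
})

test_that("data-driven aggregation merges redundant features by median", {
  set.seed(7)
  base <- matrix(abs(rnorm(30 * 3)) + 1, 30, 3)
  X <- cbind(u1 = base[, 1], u2 = base[, 1], v = base[, 2], w = base[, 3])
  em <- make_em(X)
  res <- aggregate_features(em, mode = "data_driven", tolerance = 0.1)
  expect_equal(ncol(res$data$values), 3L)
  merged_id <- names(res$map)[lengths(res$map) == 2]
  expect_equal(sort(res$map[[merged_id]]), c("u1", "u2"))
  # median of two identical columns is the column itself
  expect_equal(unname(res$data$values[, merged_id]), unname(X[, "u1"]))
  # member sets partition the original features
  expect_setequal(unlist(res$map), colnames(X))
  expect_equal(anyDuplicated(unlist(res$map)), 0L)
})

test_that("knowledge-driven aggregation collapses classes unconditionally", {
  set.seed(8)
  X <- matrix(abs(rnorm(20 * 5)) + 1, 20, 5)
  colnames(X) <- c("a", "b", "c", "x", "y")
  em <- make_em(X)
  grouping <- c(a = "AA", b = "AA", c = "AA")
  res <- aggregate_features(em, mode = "knowledge_driven",
                            grouping = grouping)
  expect_equal(ncol(res$data$values), 3L)
  expect_equal(sort(res$map[["AA"]]), c("a", "b", "c"))
  expect_equal(unname(res$data$values[, "AA"]),
               apply(X[, c("a", "b", "c")], 1, median))
  # unlisted features stay singletons under their own id
  expect_true(all(c("x", "y") %in% colnames(res$data$values)))
  expect_error(aggregate_features(em, mode = "knowledge_driven"),
               "grouping")
})

test_that("hybrid aggregation refines the knowledge partition", {
  set.seed(9)
  base <- matrix(rnorm(50 * 4), 50, 4)
  # class AA holds two correlated members and one unrelated member
  X <- exp(cbind(a1 = base[, 1], a2 = base[, 1] + rnorm(50, sd = 0.01),
                 a3 = base[, 2], z1 = base[, 3], z2 = base[, 4]))
  em <- log_transform(make_em(X))
  grouping <- c(a1 = "AA", a2 = "AA", a3 = "AA")
  hyb <- aggregate_features(em, mode = "hybrid", tolerance = 0.3,
                            grouping = grouping)
  kno <- aggregate_features(em, mode = "knowledge_driven",
                            grouping = grouping)
  # hybrid splits AA (a3 has a different profile), knowledge does not
  expect_gt(ncol(hyb$data$values), ncol(kno$data$values))
  # every hybrid group is contained in one knowledge group
  for (g in hyb$map) {
    holder <- vapply(kno$map, function(k) all(g %in% k), logical(1))
    expect_equal(sum(holder), 1L)
  }
  expect_error(aggregate_features(em, mode = "data_driven",
                                  tolerance = 3), "tolerance")
})

test_that("redundant-block fixture collapses to its latent dimension", {
  sim <- simulate_redundant_features(n = 50, n_latent = 40, p = 100,
                                     seed = 2)
  em <- log_transform(sim$data)
  res <- aggregate_features(em, mode = "data_driven", tolerance = 0.05)
  expect_equal(ncol(res$data$values), 40L)  # 60% reduction
  # recovered groups match the latent assignment
  for (members in res$map) {
    expect_length(unique(sim$latent_of[match(members,
                                             colnames(em$values))]), 1L)
  }
})

test_that("tolerance scan is monotone and recommends a usable cutoff", {
  sim <- simulate_redundant_features(n = 30, n_latent = 10, p = 40,
                                     seed = 3)
  em <- log_transform(sim$data)
  scan <- tolerance_scan(em, c(0.5, 0.1, 1.0, 2.0))
  expect_equal(scan$tolerance, c(0.1, 0.5, 1.0, 2.0))
  expect_true(all(diff(scan$effective_feature_count) <= 0))
  expect_equal(scan$effective_feature_count[4], 1L)  # full merge
  expect_equal(scan$features_to_sample_ratio,
               scan$effective_feature_count / 30)
  expect_equal(attr(scan, "recommended"), 0.1)
  expect_error(tolerance_scan(em, numeric(0)), "empty")
})
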