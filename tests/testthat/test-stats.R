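test_that("permutation t-test: identity, symmetry, power, bounds", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(permutation_ttest(x, x, B = 500, seed = 1)$p, 1)
  set.seed(61)
  a <- stats::rnorm(25)
  b <- stats::rnorm(25, 3)
  r1 <- permutation_ttest(a, b, B = 10000, seed = 2)
  r2 <- permutation_ttest(b, a, B = 10000, seed = 2)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$Z, -r2$Z, tolerance = 0.05)  # null is resampled
  expect_lte(r1$p, 0.001)                      # N(0,1) vs N(3,1), n=25
  expect_gte(r1$p, 1 / 10001)                  # never exactly zero
  expect_warning(permutation_ttest(rep(1, 5), rep(1, 5), B = 100),
                 "zero variance")
})

test_that("node-wise test: calibration, planted power, constant flagging", {
  set.seed(62)
  X <- matrix(stats::rnorm(50 * 60), 50, 60)
  labels <- rep(c("AD", "HC"), each = 25)
  res <- nodewise_group_test(X, labels, B = 1000, seed = 3)
  expect_equal(nrow(res), 60)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.06)  # null calibration
  # planted effect at node 7
  Xp <- X
  Xp[labels == "AD", 7] <- Xp[labels == "AD", 7] + 3
  resp <- nodewise_group_test(Xp, labels, B = 1000, seed = 3)
  expect_equal(which.min(resp$p), 7L)
  # constant node flagged non-significant with warning
  Xc <- X
  Xc[, 2] <- 1
  expect_warning(resc <- nodewise_group_test(Xc, labels, B = 200,
                                             seed = 3), "constant")
  expect_equal(resc$p[2], 1)
  expect_equal(resc$Z[2], 0)
  expect_error(nodewise_group_test(cbind(c(NA, X[-1, 1])), labels,
                                   B = 100), "missing")
})

test_that("node-wise agrees with the single-feature test under one schedule", {
  set.seed(63)
  x <- stats::rnorm(20)
  y <- stats::rnorm(20, 1)
  single <- permutation_ttest(x, y, B = 2000, seed = 9)
  multi <- nodewise_group_test(cbind(c(x, y)), rep(c("AD", "HC"),
                                                   each = 20),
                               B = 2000, seed = 9)
  expect_equal(multi$statistic[1], single$statistic, tolerance = 1e-12)
  # the two functions draw their permutation nulls differently (sorted
  # pooled sample vs shared label schedule), so agreement is Monte Carlo
  expect_equal(multi$p[1], single$p, tolerance = 0.05)
  expect_equal(multi$Z[1], single$Z, tolerance = 0.15)
})

test_that("FDR: m = 1 reduction, all-equal case, step-up oracle, invariance", {
  expect_true(fdr_adjust(0.04)$reject)
  expect_false(fdr_adjust(0.06)$reject)
  allp <- rep(0.001, 148)
  expect_true(all(fdr_adjust(allp)$reject))
  set.seed(64)
  for (r in 1:30) {
    p <- stats::runif(sample(5:80, 1))^sample(1:3, 1)
    got <- fdr_adjust(p, q = 0.05)
    expect_identical(got$reject, bh_stepup_oracle(p, 0.05))
    expect_true(all(diff(got$p_adjusted[order(p)]) >= -1e-12))  # monotone
    perm <- sample(length(p))
    expect_identical(fdr_adjust(p[perm])$reject, got$reject[perm])
  }
  expect_error(fdr_adjust(c(0.5, 0)), "p-values")
  expect_error(fdr_adjust(c(0.5, 1.2)), "p-values")
})

test_that("Spearman: monotone extremes, midrank ties, constant error", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_correlation(x, x^3, B = 200)$R, 1)
  expect_equal(spearman_correlation(x, -x, B = 200)$R, -1)
  set.seed(65)
  a <- sample(1:4, 30, replace = TRUE)  # heavy ties
  b <- a + sample(0:2, 30, replace = TRUE)
  got <- spearman_correlation(a, b, B = 500, seed = 5)
  expect_equal(got$R, stats::cor(rank(a), rank(b)))  # midrank oracle
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "3 pairs")
})

test_that("Kruskal-Wallis: nonnegative H, two-group equivalence, identical groups", {
  set.seed(66)
  g <- list(stats::rnorm(10), stats::rnorm(12), stats::rnorm(8))
  kw <- kruskal_wallis(g)
  expect_gte(kw$statistic, 0)
  expect_equal(kw$df, 2)
  # two groups: H equals the squared standardized rank-sum statistic
  a <- stats::rnorm(9)
  b <- stats::rnorm(11, 0.5)
  kw2 <- kruskal_wallis(list(a, b))
  rks <- rank(c(a, b))
  n <- 20
  R1 <- sum(rks[1:9])
  mu <- 9 * (n + 1) / 2
  sig2 <- 9 * 11 * (n + 1) / 12
  expect_equal(kw2$statistic, (R1 - mu)^2 / sig2, tolerance = 1e-10)
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 6)))$statistic, 0)
})

test_that("Kruskal-Wallis p is calibrated under the null", {
  set.seed(67)
  ps <- replicate(200, kruskal_wallis(
    list(stats::rnorm(8), stats::rnorm(8), stats::rnorm(8)))$p)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.1)
  expect_lt(abs(mean(ps < 0.75) - 0.75), 0.1)
})

test_that("hierarchical gate: pursue only globally significant features", {
  set.seed(68)
  n <- 40
  labels <- rep(c("AD", "HC"), each = n / 2)
  null_g <- stats::rnorm(n)
  eff_g <- c(stats::rnorm(n / 2, 2), stats::rnorm(n / 2))
  null_l <- matrix(stats::rnorm(n * 10), n, 10)
  eff_l <- null_l
  eff_l[labels == "AD", 3] <- eff_l[labels == "AD", 3] + 2
  res <- hierarchical_test(
    global_features = list(flat = null_g, shifted = eff_g),
    local_features = list(flat = null_l, shifted = eff_l),
    labels = labels, B = 500, seed = 6)
  expect_false(res$flat$pursued)
  expect_null(res$flat$local)
  expect_true(res$shifted$pursued)
  expect_true(all(c("p_adjusted", "significant") %in%
                    names(res$shifted$local)))
  expect_equal(which.min(res$shifted$local$p), 3L)
})
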