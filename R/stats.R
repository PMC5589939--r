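# Group statistics: permutation t-tests with permutation Z-scores, FDR
# control, Spearman correlation with permutation p-values, Kruskal-Wallis
# profiling, and the hierarchical global -> local testing scheme.

two_sample_t <- function(s1, q1, n1, s2, q2, n2) {
  # t from group sums (s) and sums of squares (q); pooled-variance form
  m1 <- s1 / n1
  m2 <- s2 / n2
  sp2 <- (q1 - s1^2 / n1 + q2 - s2^2 / n2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  ifelse(se > 0, (m1 - m2) / se, 0)
}

#' Two-sample permutation t-test
#'
#' Computes the pooled-variance two-sample t statistic for `x` vs `y` and
#' its permutation null by randomly exchanging group labels `B` times. The
#' two-sided p-value uses the add-one convention
#' `p = (1 + #\{|t*| >= |t|\}) / (B + 1)` (never exactly zero), and the Z
#' score standardizes the observed t against the permutation null's mean
#' and sd.
#'
#' @param x,y numeric samples (e.g. AD then HC feature values); the
#'   statistic has sign mean(x) - mean(y).
#' @param B number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return Object of class `stat_result`: `statistic`, `Z`, `p`,
#'   `n_permutations`.
#' @export
permutation_ttest <- function(x, y, B = 10000L, seed = 1L) {
  if (length(x) < 2 || length(y) < 2)
    stop_mfnet("both groups need at least 2 observations")
  if (any(!is.finite(c(x, y)))) stop_mfnet("non-finite values in input")
  z <- c(x, y)
  n1 <- length(x)
  n <- length(z)
  if (stats::var(z) == 0) {
    warning("zero variance in both groups; p = 1, Z = 0")
    return(structure(list(statistic = 0, Z = 0, p = 1,
                          n_permutations = B), class = "stat_result"))
  }
  t_obs <- two_sample_t(sum(x), sum(x^2), n1, sum(y), sum(y^2), n - n1)
  # the null is built from the sorted pooled sample: the same permutation
  # distribution, but invariant to the order (and swap) of the two inputs
  z <- sort(z)
  z2 <- z^2
  S <- sum(z)
  Q <- sum(z2)
  set.seed(seed)
  t_null <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n1)
    s1 <- sum(z[i])
    q1 <- sum(z2[i])
    t_null[b] <- two_sample_t(s1, q1, n1, S - s1, Q - q1, n - n1)
  }
  p <- (1 + sum(abs(t_null) >= abs(t_obs) - 1e-12)) / (B + 1)
  sdn <- stats::sd(t_null)
  Z <- if (sdn > 0) (t_obs - mean(t_null)) / sdn else 0
  structure(list(statistic = t_obs, Z = Z, p = p, n_permutations = B),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> t =", round(x$statistic, 4), " Z =", round(x$Z, 4),
      " p =", signif(x$p, 4), " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Node-wise permutation t-tests
#'
#' Runs the permutation t-test of [permutation_ttest()] at every node
#' (column) of a subjects x nodes feature table. A single permutation
#' schedule, drawn once from `seed`, is shared across all nodes: this keeps
#' the node-wise nulls jointly exchangeable and makes the whole call cost
#' O(B) group sums instead of O(B * nodes) independent draws.
#'
#' @param features numeric matrix, subjects x nodes; no missing values.
#' @param labels group label per subject (two levels).
#' @param case label treated as the first group (statistic sign
#'   mean(case) - mean(other)); default `"AD"`.
#' @param B number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return data.frame with one row per node: `node` (1-based column
#'   index), `statistic`, `Z`, `p`.
#' @export
nodewise_group_test <- function(features, labels, case = "AD",
                                B = 10000L, seed = 1L) {
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    stop_mfnet("feature table contains missing or non-finite values")
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop_mfnet("one label per subject required")
  if (!case %in% labels) stop_mfnet("case label '", case, "' not present")
  if (length(unique(labels)) != 2) stop_mfnet("exactly two groups required")
  idx1 <- which(labels == case)
  n1 <- length(idx1)
  n <- nrow(features)
  if (n1 < 2 || n - n1 < 2) stop_mfnet("each group needs >= 2 subjects")
  X <- features
  X2 <- X^2
  S <- colSums(X)
  Q <- colSums(X2)
  s1 <- colSums(X[idx1, , drop = FALSE])
  q1 <- colSums(X2[idx1, , drop = FALSE])
  t_obs <- two_sample_t(s1, q1, n1, S - s1, Q - q1, n - n1)
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const))
    warning(sum(const), " node(s) have constant features; flagged with ",
            "p = 1")
  set.seed(seed)
  exceed <- numeric(ncol(X))
  sum_t <- numeric(ncol(X))
  sum_t2 <- numeric(ncol(X))
  for (b in seq_len(B)) {
    i <- sample.int(n, n1)
    sb <- colSums(X[i, , drop = FALSE])
    qb <- colSums(X2[i, , drop = FALSE])
    tb <- two_sample_t(sb, qb, n1, S - sb, Q - qb, n - n1)
    exceed <- exceed + (abs(tb) >= abs(t_obs) - 1e-12)
    sum_t <- sum_t + tb
    sum_t2 <- sum_t2 + tb^2
  }
  p <- (1 + exceed) / (B + 1)
  mu <- sum_t / B
  sdn <- sqrt(pmax(sum_t2 / B - mu^2, 0) * B / (B - 1))
  Z <- ifelse(sdn > 0, (t_obs - mu) / sdn, 0)
  p[const] <- 1
  Z[const] <- 0
  data.frame(node = seq_len(ncol(X)), statistic = t_obs, Z = Z, p = p)
}

#' False discovery rate adjustment
#'
#' Step-up FDR control over a vector of p-values: Benjamini-Hochberg by
#' default, Benjamini-Yekutieli (valid under arbitrary dependence) as a
#' variant. Adjusted p-values are monotone in the raw p-values; a feature
#' is rejected when its adjusted p is at most `q`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param q target FDR level (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_adjust <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_mfnet("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stop_mfnet("q must lie in (0, 1)")
  adj <- stats::p.adjust(p, method = method)
  list(p_adjusted = adj, reject = adj <= q)
}

#' Spearman correlation with permutation p-value
#'
#' Spearman's rank correlation R between a network feature and a score,
#' with a two-sided p-value from `B` random permutations of the score
#' order (consistent with the permutation framework used for the group
#' tests, rather than the t-approximation).
#'
#' @param feature,score paired numeric vectors, length >= 3.
#' @param B permutations (default 10000).
#' @param seed integer RNG seed.
#' @return List with `R` and `p`.
#' @export
spearman_correlation <- function(feature, score, B = 10000L, seed = 1L) {
  if (length(feature) != length(score))
    stop_mfnet("feature and score must be paired")
  n <- length(feature)
  if (n < 3) stop_mfnet("need at least 3 pairs")
  if (stats::sd(feature) == 0 || stats::sd(score) == 0)
    stop_mfnet("constant input: Spearman R undefined")
  rf <- rank(feature)
  rs <- rank(score)
  R <- stats::cor(rf, rs)
  u <- (rf - mean(rf)) / stats::sd(rf)
  v <- (rs - mean(rs)) / stats::sd(rs)
  set.seed(seed)
  V <- vapply(seq_len(B), function(b) v[sample.int(n)], numeric(n))
  Rstar <- as.numeric(crossprod(u, V)) / (n - 1)
  p <- (1 + sum(abs(Rstar) >= abs(R) - 1e-12)) / (B + 1)
  list(R = R, p = p)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based one-way comparison of two or more samples, with the standard
#' tie correction and a chi-squared approximation on (#groups - 1) degrees
#' of freedom. Used here to test whether a node's degree proportions
#' differ across frequency-band layers.
#'
#' @param groups list of numeric vectors, one per group.
#' @return List with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop_mfnet("need a list of >= 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop_mfnet("every group needs at least one value")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(list(statistic = 0, df = length(groups) - 1, p = 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Hierarchical global-to-local group testing
#'
#' Screens each network feature at the global (whole-network) scale with a
#' permutation t-test; only features significant at `alpha` are pursued at
#' the local (node) scale, where node-wise permutation tests are corrected
#' by FDR at level `q`. This limits the number of node-level comparisons
#' to features already showing a system-level difference.
#'
#' @param global_features named list of per-subject numeric vectors (one
#'   global value per subject per feature).
#' @param local_features named list (same names) of subjects x nodes
#'   matrices.
#' @param labels group label per subject.
#' @param case case-group label (default `"AD"`).
#' @param B permutations per test (default 10000).
#' @param alpha global-scale significance level (default 0.05).
#' @param q FDR level for the local scale (default 0.05).
#' @param seed integer RNG seed.
#' @return Named list per feature: `global` (`stat_result`), `pursued`
#'   (logical), and `local` (data.frame with FDR columns, or NULL when not
#'   pursued).
#' @export
hierarchical_test <- function(global_features, local_features, labels,
                              case = "AD", B = 10000L, alpha = 0.05,
                              q = 0.05, seed = 1L) {
  if (is.null(names(global_features)))
    stop_mfnet("global_features must be a named list")
  labels <- as.character(labels)
  out <- list()
  for (f in names(global_features)) {
    gv <- global_features[[f]]
    if (length(gv) != length(labels))
      stop_mfnet("feature '", f, "': one value per subject required")
    gres <- permutation_ttest(gv[labels == case], gv[labels != case],
                              B = B, seed = seed)
    pursued <- gres$p < alpha
    local <- NULL
    if (pursued) {
      if (is.null(local_features[[f]]))
        stop_mfnet("feature '", f, "' significant globally but no local ",
                   "features supplied")
      local <- nodewise_group_test(local_features[[f]], labels, case = case,
                                   B = B, seed = seed)
      fa <- fdr_adjust(local$p, q = q)
      local$p_adjusted <- fa$p_adjusted
      local$significant <- fa$reject
    }
    out[[f]] <- list(global = gres, pursued = pursued, local = local)
  }
  out
}
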