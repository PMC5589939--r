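# Diagnostic classification: p-value-ranked feature vectors, a Mahalanobis
# distance classifier, repeated stratified cross-validation, ROC/AUC, and
# a grid search over feature-family combinations.

#' Rank nodes by group-difference significance
#'
#' Orders ROIs by ascending p-value; ties broken by larger |Z| first, then
#' by node index. The resulting order defines the feature vector
#' `c_s = [g_1, ..., g_k]` used for classification, g_1 being the most
#' significant ROI.
#'
#' @param stats data.frame from [nodewise_group_test()] (columns `node`,
#'   `Z`, `p`).
#' @return Integer vector of node indices in rank order.
#' @export
rank_features <- function(stats) {
  if (!all(c("node", "p", "Z") %in% names(stats)))
    stop_mfnet("expected columns node, Z, p")
  stats$node[order(stats$p, -abs(stats$Z), stats$node)]
}

pooled_within_class_cov <- function(x, y, classes) {
  n <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  covs <- lapply(classes, function(cl)
    stats::cov(x[y == cl, , drop = FALSE]))
  Reduce(`+`, Map(function(S, ni) (ni - 1) * S, covs, n)) / (sum(n) - 2)
}

#' Mahalanobis distance classifier
#'
#' Assigns each test subject to the class whose mean is closest in
#' Mahalanobis distance under the pooled within-class covariance. When the
#' covariance is ill-conditioned (feature count approaching the training
#' size) a ridge `lambda * I` with `lambda = 1e-6 * trace / dim` is added
#' automatically if `regularize = TRUE`; otherwise a singular covariance is
#' an error advising shrinkage. The returned `score`,
#' `d^2(other) - d^2(case)`, grows with case-likeness and feeds the ROC.
#'
#' @param train_x,train_y training feature matrix (subjects x features) and
#'   labels (exactly two classes, >= 2 subjects each).
#' @param test_x test feature matrix with the same columns.
#' @param case label of the positive class (default `"AD"`).
#' @param regularize apply automatic ridge shrinkage when needed (default
#'   TRUE).
#' @return List with `pred` (labels), `distances` (squared distances,
#'   columns = classes), `score`.
#' @export
mahalanobis_classify <- function(train_x, train_y, test_x, case = "AD",
                                 regularize = TRUE) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  classes <- sort(unique(train_y))
  if (length(classes) != 2) stop_mfnet("exactly two classes required")
  if (any(table(train_y) < 2))
    stop_mfnet("need >= 2 training subjects per class")
  if (!case %in% classes) stop_mfnet("case label '", case, "' not in labels")
  S <- pooled_within_class_cov(train_x, train_y, classes)
  d <- ncol(train_x)
  ok <- function(M) {
    r <- tryCatch(rcond(M), error = function(e) 0)
    is.finite(r) && r > 1e-12
  }
  if (!ok(S)) {
    if (!regularize)
      stop_mfnet("pooled covariance is singular or ill-conditioned; ",
                 "enable regularize = TRUE for ridge shrinkage or reduce ",
                 "the feature count")
    S <- S + diag(1e-6 * sum(diag(S)) / d, d)
    if (!ok(S)) S <- S + diag(1e-6 * max(sum(diag(S)) / d, 1), d)
  }
  dist2 <- vapply(classes, function(cl) {
    mu <- colMeans(train_x[train_y == cl, , drop = FALSE])
    stats::mahalanobis(test_x, mu, S)
  }, numeric(nrow(test_x)))
  dist2 <- matrix(dist2, nrow = nrow(test_x),
                  dimnames = list(NULL, classes))
  pred <- classes[max.col(-dist2, ties.method = "first")]
  other <- setdiff(classes, case)
  list(pred = pred, distances = dist2,
       score = dist2[, other] - dist2[, case])
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the scores (predict `case` when
#' `score >= threshold`) and integrates the resulting ROC curve by the
#' trapezoid rule; tied scores contribute diagonal segments, so the AUC
#' equals the probability of correct pairwise ordering with ties counted
#' one half.
#'
#' @param scores numeric vector, larger = more case-like.
#' @param labels class label per score.
#' @param case positive-class label (default `"AD"`).
#' @return List with `roc` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, case = "AD") {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop_mfnet("one label per score required")
  pos <- labels == case
  if (!any(pos) || all(pos))
    stop_mfnet("both classes must be present to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  # one ROC point after each distinct score value
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / sum(pos))
  fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[last])),
       auc = auc)
}

# Shared CV engine. `builder(train_idx, test_idx)` returns list(train_x,
# test_x) so callers can rank features inside the training split without
# touching test rows.
cv_engine <- function(builder, labels, case, n_iter, train_frac, seed,
                      mode = c("split", "kfold"), regularize = TRUE) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_mfnet("exactly two classes required")
  other <- setdiff(classes, case)
  idx_by <- split(seq_along(labels), labels)
  set.seed(seed)
  acc <- sens <- spec <- numeric(0)
  all_scores <- numeric(0)
  all_labels <- character(0)
  redraws <- 0L
  eval_split <- function(train_idx, test_idx) {
    fit <- mahalanobis_classify(feat$train_x, labels[train_idx],
                                feat$test_x, case = case,
                                regularize = regularize)
    truth <- labels[test_idx]
    acc <<- c(acc, 100 * mean(fit$pred == truth))
    if (any(truth == case))
      sens <<- c(sens, 100 * mean(fit$pred[truth == case] == case))
    if (any(truth == other))
      spec <<- c(spec, 100 * mean(fit$pred[truth == other] == other))
    all_scores <<- c(all_scores, fit$score)
    all_labels <<- c(all_labels, truth)
  }
  for (it in seq_len(n_iter)) {
    if (mode == "split") {
      repeat {
        train_idx <- sort(unlist(lapply(idx_by, function(ix)
          sample(ix, round_half_up(train_frac * length(ix))))))
        test_idx <- setdiff(seq_along(labels), train_idx)
        n_tr <- table(labels[train_idx])
        if (length(test_idx) > 0 && length(n_tr) == 2 && all(n_tr >= 2))
          break
        redraws <- redraws + 1L
      }
      feat <- builder(train_idx, test_idx)
      eval_split(train_idx, test_idx)
    } else {
      folds <- integer(length(labels))
      for (ix in idx_by) folds[sample(ix)] <- rep_len(1:5, length(ix))
      for (f in 1:5) {
        test_idx <- which(folds == f)
        train_idx <- which(folds != f)
        if (!length(test_idx)) next
        feat <- builder(train_idx, test_idx)
        eval_split(train_idx, test_idx)
      }
    }
  }
  ra <- roc_auc(all_scores, all_labels, case = case)
  structure(list(acc = mean(acc), sens = mean(sens), spec = mean(spec),
                 auc = ra$auc, roc = ra$roc, n_iter = n_iter,
                 acc_sd = stats::sd(acc), redraws = redraws,
                 case = case),
            class = "classifier_performance")
}

#' @export
print.classifier_performance <- function(x, ...) {
  cat(sprintf(
    "<classifier_performance> Acc %.2f%%  Sens %.2f%%  Spec %.2f%%  AUC %.4f  (%d iterations)\n",
    x$acc, x$sens, x$spec, x$auc, x$n_iter))
  invisible(x)
}

#' Repeated cross-validated Mahalanobis classification
#'
#' Repeatedly splits the cohort into a stratified 80% training / 20% test
#' partition (a 5-fold-sized test set), fits the Mahalanobis classifier on
#' the training part and scores the held-out part; Acc/Sens/Spec are
#' averaged over iterations and the ROC/AUC is computed from the pooled
#' held-out scores. `mode = "kfold"` instead performs classical stratified
#' 5-fold CV, repeated `n_iter` times. Splits in which a training class
#' would drop below 2 subjects are redrawn (count reported).
#'
#' @param features subjects x features numeric matrix.
#' @param labels class label per subject (two classes).
#' @param n_iter iterations (default 1000; raise to 10000 for final runs).
#' @param train_frac training fraction for `mode = "split"` (default 0.8).
#' @param seed integer RNG seed.
#' @param case positive-class label (default `"AD"`).
#' @param mode `"split"` (default) or `"kfold"`.
#' @return A `classifier_performance`: `acc`, `sens`, `spec` (percent),
#'   `auc`, `roc`, `acc_sd`, `redraws`.
#' @export
repeated_cv <- function(features, labels, n_iter = 1000L, train_frac = 0.8,
                        seed = 1L, case = "AD",
                        mode = c("split", "kfold")) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop_mfnet("one label per subject required")
  builder <- function(train_idx, test_idx)
    list(train_x = features[train_idx, , drop = FALSE],
         test_x = features[test_idx, , drop = FALSE])
  cv_engine(builder, labels, case, n_iter, train_frac, seed,
            mode = match.arg(mode))
}

# Fast parametric t p-values per column, used only to rank features inside
# a training fold (a permutation test per split would be prohibitive).
column_t_pvalues <- function(x, labels, case) {
  idx1 <- labels == case
  n1 <- sum(idx1)
  n2 <- sum(!idx1)
  s1 <- colSums(x[idx1, , drop = FALSE])
  q1 <- colSums(x[idx1, , drop = FALSE]^2)
  s2 <- colSums(x[!idx1, , drop = FALSE])
  q2 <- colSums(x[!idx1, , drop = FALSE]^2)
  t <- two_sample_t(s1, q1, n1, s2, q2, n2)
  2 * stats::pt(-abs(t), df = n1 + n2 - 2)
}

#' Grid search over ranked feature-family combinations
#'
#' For every pair (k1, k2) with k1 in 0..max_k_each and k2 likewise (the
#' empty (0, 0) cell excluded), concatenates the top-k1 nodes of the first
#' feature family (e.g. single-layer PC in one band) with the top-k2 nodes
#' of the second (e.g. MPC) and evaluates the combination by
#' [repeated_cv()]. With `rank = "in_fold"` (default) the node ranking is
#' recomputed inside every training split from two-sample t p-values, so
#' no test information leaks into feature selection; `rank = "whole"`
#' ranks once on the full sample (the optimistic variant, for comparison).
#'
#' @param family1,family2 subjects x nodes matrices of the two feature
#'   families.
#' @param labels class label per subject.
#' @param max_k_each largest number of ranked nodes per family (default 5).
#' @param n_iter CV iterations per cell (default 200).
#' @param seed integer RNG seed.
#' @param case positive-class label (default `"AD"`).
#' @param rank `"in_fold"` (default) or `"whole"`.
#' @param train_frac training fraction (default 0.8).
#' @return List with matrices `acc`, `sens`, `spec`, `auc` (rows k1 = 0..,
#'   columns k2 = 0..; the (0,0) cell is NA) and `best`, the
#'   argmax-accuracy cell `(k1, k2, acc)`.
#' @export
feature_grid_search <- function(family1, family2, labels, max_k_each = 5L,
                                n_iter = 200L, seed = 1L, case = "AD",
                                rank = c("in_fold", "whole"),
                                train_frac = 0.8) {
  rank <- match.arg(rank)
  family1 <- as.matrix(family1)
  family2 <- as.matrix(family2)
  labels <- as.character(labels)
  if (max_k_each < 1) stop_mfnet("max_k_each must be >= 1")
  if (max_k_each > min(ncol(family1), ncol(family2)))
    stop_mfnet("max_k_each exceeds available nodes")
  dims <- max_k_each + 1L
  nm <- list(paste0("k1_", 0:max_k_each), paste0("k2_", 0:max_k_each))
  acc <- sens <- spec <- auc <- matrix(NA_real_, dims, dims, dimnames = nm)
  whole1 <- order(column_t_pvalues(family1, labels, case))
  whole2 <- order(column_t_pvalues(family2, labels, case))
  best <- list(k1 = NA, k2 = NA, acc = -Inf)
  for (k1 in 0:max_k_each) {
    for (k2 in 0:max_k_each) {
      if (k1 == 0 && k2 == 0) next
      builder <- function(train_idx, test_idx) {
        if (rank == "in_fold") {
          o1 <- order(column_t_pvalues(family1[train_idx, , drop = FALSE],
                                       labels[train_idx], case))
          o2 <- order(column_t_pvalues(family2[train_idx, , drop = FALSE],
                                       labels[train_idx], case))
        } else {
          o1 <- whole1
          o2 <- whole2
        }
        cols1 <- o1[seq_len(k1)]
        cols2 <- o2[seq_len(k2)]
        list(train_x = cbind(family1[train_idx, cols1, drop = FALSE],
                             family2[train_idx, cols2, drop = FALSE]),
             test_x = cbind(family1[test_idx, cols1, drop = FALSE],
                            family2[test_idx, cols2, drop = FALSE]))
      }
      perf <- cv_engine(builder, labels, case, n_iter, train_frac, seed)
      acc[k1 + 1, k2 + 1] <- perf$acc
      sens[k1 + 1, k2 + 1] <- perf$sens
      spec[k1 + 1, k2 + 1] <- perf$spec
      auc[k1 + 1, k2 + 1] <- perf$auc
      if (perf$acc > best$acc) best <- list(k1 = k1, k2 = k2,
                                            acc = perf$acc)
    }
  }
  list(acc = acc, sens = sens, spec = spec, auc = auc, best = best)
}
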