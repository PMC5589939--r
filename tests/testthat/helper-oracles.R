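# Fixture generators and independent brute-force oracles. Oracles are
# written from the definitions directly (loops, enumeration, pair counts)
# and never call the package code paths they check.

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

random_multiplex <- function(n, M, p = 0.4) {
  build_multiplex(stats::setNames(
    lapply(seq_len(M), function(i) random_adjacency(n, p)),
    paste0("L", seq_len(M))))
}

# Eq.-by-eq participation coefficient: recount per-module links node by node.
pc_oracle <- function(A, memb) {
  n <- nrow(A)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(A[i, ])
    if (k_i == 0) next
    s <- 0
    for (m in unique(memb)) {
      k_im <- sum(A[i, memb == m])
      s <- s + (k_im / k_i)^2
    }
    pc[i] <- 1 - s
  }
  pc
}

# Direct evaluation of the multiplex participation formula per node.
mpc_oracle <- function(layers) {
  n <- nrow(layers[[1]])
  M <- length(layers)
  mpc <- numeric(n)
  for (i in seq_len(n)) {
    k <- vapply(layers, function(L) sum(L[i, ]), numeric(1))
    o <- sum(k)
    if (o == 0) next
    mpc[i] <- M / (M - 1) * (1 - sum((k / o)^2))
  }
  mpc
}

nlp_oracle <- function(layers) {
  n <- nrow(layers[[1]])
  t(vapply(seq_len(n), function(i) {
    k <- vapply(layers, function(L) sum(L[i, ]), numeric(1))
    o <- sum(k)
    if (o == 0) rep(0, length(layers)) else k / o
  }, numeric(length(layers))))
}

# All set partitions of n items as restricted growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_label) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_label)) rec(c(labels, l),
                                       next_label + (l == next_label))
  }
  rec(integer(0), 1L)
  out
}

# Newman-Girvan modularity from its definition.
modularity_oracle_q <- function(A, memb) {
  m2 <- sum(A)
  if (m2 == 0) return(NA_real_)
  k <- rowSums(A)
  same <- outer(memb, memb, `==`)
  sum((A - outer(k, k) / m2) * same) / m2
}

# Exhaustive best-partition modularity for small graphs.
max_modularity_oracle <- function(A) {
  best <- -Inf
  for (memb in enumerate_partitions(nrow(A))) {
    q <- modularity_oracle_q(A, memb)
    if (q > best) best <- q
  }
  best
}

# Literal Benjamini-Hochberg step-up: largest i with p_(i) <= i*q/m.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  imax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) imax <- i
  reject <- rep(FALSE, m)
  if (imax > 0) reject[o[seq_len(imax)]] <- TRUE
  reject
}

# AUC as normalized correctly-ordered pair count (ties count one half).
auc_pair_oracle <- function(scores, labels, case = "AD") {
  sp <- scores[labels == case]
  sn <- scores[labels != case]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Per-subject global MPC after thresholding every band at mean degree k.
cohort_global_mpc <- function(cohort, k = 12) {
  vapply(cohort$connectomes, function(bc) {
    mx <- build_multiplex(lapply(bc$matrices, threshold_to_mean_degree,
                                 k = k))
    multi_participation_coefficient(mx)$global
  }, numeric(1))
}

# Per-subject node-level MPC matrix (subjects x nodes) at threshold k.
cohort_local_mpc <- function(cohort, k = 12) {
  t(vapply(cohort$connectomes, function(bc) {
    mx <- build_multiplex(lapply(bc$matrices, threshold_to_mean_degree,
                                 k = k))
    multi_participation_coefficient(mx)$mpc
  }, numeric(cohort$connectomes[[1]]$n_nodes)))
}

small_test_spec <- function(seed = 1L, delta = 0, n_per_group = 25) {
  cohort_spec(n_hc = n_per_group, n_ad = n_per_group, n_nodes = 40,
              module_sizes = rep(10, 4), delta = delta,
              affected_nodes = 1:10, seed = seed)
}
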