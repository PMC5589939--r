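test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_nodes = 40, module_sizes = c(10, 10)),
               "module_sizes")
  expect_error(cohort_spec(w_in = 0.3, w_out = 0.5), "w_out < w_in")
  expect_error(cohort_spec(delta = 1), "delta")
  expect_error(cohort_spec(delta = -0.1), "delta")
  expect_error(cohort_spec(n_nodes = 20, module_sizes = rep(5, 4),
                           affected_nodes = 25), "affected_nodes")
  sp <- cohort_spec(n_nodes = 148)
  expect_equal(sum(sp$module_sizes), 148)
})

test_that("generated matrices are symmetric, zero-diagonal, in [0,1]", {
  sp <- small_test_spec(seed = 51, delta = 0.5)
  for (grp in c("HC", "AD")) {
    bc <- generate_subject_connectome(sp, grp, subject_seed = 7)
    expect_length(bc$matrices, 7)
    for (m in bc$matrices) {
      expect_equal(m, t(m))
      expect_true(all(diag(m) == 0))
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("planted partition puts heavier weight within modules", {
  sp <- small_test_spec(seed = 52)
  bc <- generate_subject_connectome(sp, "HC", subject_seed = 1)
  memb <- rep(1:4, each = 10)
  same <- outer(memb, memb, `==`) & upper.tri(diag(40))
  across <- !outer(memb, memb, `==`) & upper.tri(diag(40))
  m <- bc$matrices$delta
  expect_gt(mean(m[same]), mean(m[across]))
  expect_equal(mean(m[same]), sp$w_in, tolerance = 0.02)
  expect_equal(mean(m[across]), sp$w_out, tolerance = 0.02)
})

test_that("per-subject seeding makes cohorts reproducible element-wise", {
  sp <- small_test_spec(seed = 53, n_per_group = 3)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(c1$connectomes[["AD002"]]$matrices$gamma,
               c2$connectomes[["AD002"]]$matrices$gamma)
  # changing the cohort seed changes the draws
  sp2 <- small_test_spec(seed = 54, n_per_group = 3)
  expect_false(identical(generate_cohort(sp2)$connectomes[["AD002"]],
                         c1$connectomes[["AD002"]]))
})

test_that("delta = 0 makes groups identically distributed; HC layers balanced", {
  sp <- small_test_spec(seed = 55)
  # with the same subject seed, AD and HC draws coincide exactly at delta=0
  expect_equal(generate_subject_connectome(sp, "AD", 3)$matrices,
               generate_subject_connectome(sp, "HC", 3)$matrices)
  # noiseless HC subject: every layer identical, NLP = 1/M for all nodes
  spn <- cohort_spec(n_hc = 2, n_ad = 2, n_nodes = 20,
                     module_sizes = rep(5, 4), weight_noise_sd = 0,
                     delta = 0, seed = 56)
  bc <- generate_subject_connectome(spn, "HC", 1)
  layers <- lapply(bc$matrices, threshold_to_mean_degree, k = 4)
  nlp <- node_degree_layer_proportion(build_multiplex(layers))
  connected <- rowSums(layers[[1]]) > 0
  expect_true(all(abs(nlp[connected, ] - 1 / 7) < 1e-12))
})

test_that("AD imbalance lowers affected-node MPC (Monte Carlo)", {
  sp <- cohort_spec(n_hc = 1, n_ad = 1, n_nodes = 40,
                    module_sizes = rep(10, 4), delta = 0.5,
                    affected_nodes = 1:10, seed = 57)
  mean_affected_mpc <- function(grp) {
    vals <- vapply(1:100, function(i) {
      bc <- generate_subject_connectome(sp, grp, split_seed(57, i))
      mx <- build_multiplex(lapply(bc$matrices, threshold_to_mean_degree,
                                   k = 12))
      mean(multi_participation_coefficient(mx)$mpc[1:10])
    }, numeric(1))
    mean(vals)
  }
  expect_lt(mean_affected_mpc("AD"), mean_affected_mpc("HC"))
})

test_that("score generation: monotone map, determinism, length checks", {
  sp <- cohort_spec(n_hc = 5, n_ad = 5, n_nodes = 20,
                    module_sizes = rep(5, 4), score_noise_sd = 0,
                    score_slope = 2, score_intercept = 1, seed = 58)
  co <- generate_cohort(sp, scores = FALSE)
  feat <- seq(0.1, 1, length.out = 10)
  co1 <- generate_scores(co, feat, sp)
  expect_equal(stats::cor(feat, co1$subjects$TR, method = "spearman"), 1)
  expect_equal(co1$subjects$TR, 1 + 2 * feat)
  co2 <- generate_scores(co, feat, sp)
  expect_identical(co1$subjects, co2$subjects)  # fixed seed twice
  expect_error(generate_scores(co, feat[-1], sp), "9 values")
})

test_that("slope 0 gives a null Spearman distribution centered at 0", {
  sp <- cohort_spec(n_hc = 10, n_ad = 10, n_nodes = 20,
                    module_sizes = rep(5, 4), score_slope = 0,
                    score_noise_sd = 1, seed = 59)
  co <- generate_cohort(sp, scores = FALSE)
  rs <- vapply(1:50, function(i) {
    sp$seed <- i
    feat <- stats::runif(20)
    stats::cor(feat, generate_scores(co, feat, sp)$subjects$TR,
               method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  expect_gt(stats::sd(rs), 0.05)  # genuinely dispersed around zero
})

test_that("band signal generator: coupling raises band coherence in order", {
  mean_band_coh <- function(strength, noise_sd = 0.5) {
    x <- generate_band_signals(
      2, fs = 200, duration = 30,
      coupling = list(list(pair = c(1, 2), band = "theta",
                           strength = strength)),
      seed = 60, noise_sd = noise_sd)
    bc <- band_average(coherence_matrix(x, 200, window_s = 2, nfft = 400))
    bc$matrices$theta[1, 2]
  }
  c0 <- mean_band_coh(0)
  c5 <- mean_band_coh(0.5)
  c1 <- mean_band_coh(1)
  expect_lt(c0, c5)
  expect_lt(c5, c1)
  # strength 1, no broadband noise: shared component, coherence ~ 1
  expect_gt(mean_band_coh(1, noise_sd = 0), 0.99)
  expect_error(generate_band_signals(2, 200, 5, coupling = list(
    list(pair = c(1, 2), band = "ripple", strength = 0.5))), "unknown band")
})
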