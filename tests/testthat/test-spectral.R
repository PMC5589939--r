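make_sc <- function(freq, mats) {
  structure(list(freq = freq,
                 coh = array(unlist(mats), dim = c(dim(mats[[1]]),
                                                   length(mats))),
                 measure = "coherence"),
            class = "spectral_connectome")
}

test_that("welch_psd: bin spacing, peak location, Parseval", {
  t <- seq(0, 4 - 1e-3, by = 1e-3)
  x <- cbind(sin(2 * pi * 10 * t))
  p <- welch_psd(x, fs = 1000, nfft = 2000)
  expect_equal(diff(p$freq[1:2]), 0.5)        # fs/nfft = 0.5 Hz
  expect_equal(p$freq[which.max(p$psd)], 10)  # peak at 10 Hz
  expect_true(all(p$psd >= 0))
  set.seed(41)
  w <- cbind(stats::rnorm(8000))
  pw <- welch_psd(w, fs = 1000, nfft = 2000)
  df <- diff(pw$freq[1:2])
  expect_equal(sum(pw$psd) * df, stats::var(w[, 1]), tolerance = 0.1)
})

test_that("welch_psd errors name the required minimum window", {
  expect_error(welch_psd(cbind(stats::rnorm(100)), fs = 1000),
               "at least 2000")
  expect_error(welch_psd(cbind(stats::rnorm(3000)), fs = 1000,
                         nfft = 1000), "nfft")
})

test_that("coherence: identical signals give 1, degenerate input errors", {
  set.seed(42)
  x <- stats::rnorm(4000)
  sc <- coherence_matrix(cbind(x, x), fs = 200, window_s = 2, nfft = 400)
  offdiag <- sc$coh[1, 2, ]
  expect_true(all(abs(offdiag - 1) < 1e-8))
  expect_true(all(diag(sc$coh[, , 10]) == 0))
  # a single segment would give coherence identically 1
  expect_error(coherence_matrix(cbind(x[1:400], x[1:400]), fs = 200,
                                window_s = 2, nfft = 400), "2 Welch segments")
  expect_error(coherence_matrix(cbind(x), fs = 200, nfft = 400),
               "2 ROIs")
})

test_that("independent-noise coherence is small and shrinks with segments", {
  set.seed(43)
  mean_coh <- vapply(c(2000, 16000), function(nsamp) {
    mean(replicate(5, {
      x <- matrix(stats::rnorm(2 * nsamp), ncol = 2)
      sc <- coherence_matrix(x, fs = 200, window_s = 2, nfft = 400)
      mean(sc$coh[1, 2, ])
    }))
  }, numeric(1))
  expect_lt(mean_coh[2], mean_coh[1])  # more segments, less bias
  expect_lt(mean_coh[2], 0.1)
})

test_that("coupled pairs out-cohere uncoupled pairs in their band", {
  x <- generate_band_signals(
    3, fs = 200, duration = 40,
    coupling = list(list(pair = c(1, 2), band = "alpha1", strength = 1)),
    seed = 44, noise_sd = 0.3)
  bc <- band_average(coherence_matrix(x, fs = 200, window_s = 2,
                                      nfft = 400))
  expect_gt(bc$matrices$alpha1[1, 2], bc$matrices$alpha1[1, 3])
  expect_gt(bc$matrices$alpha1[1, 2], 0.8)
})

test_that("imaginary coherence: zero-lag removal and quadrature detection", {
  set.seed(45)
  x <- stats::rnorm(4000)
  sc <- imaginary_coherence_matrix(cbind(x, x), fs = 200, window_s = 2,
                                   nfft = 400)
  expect_true(all(sc$coh[1, 2, ] < 1e-8))  # identical signals -> 0
  t <- seq_len(12000) / 200
  s <- sin(2 * pi * 10 * t)
  c90 <- cos(2 * pi * 10 * t)  # 90 degrees out of phase
  y <- cbind(s + 0.05 * stats::rnorm(length(t)),
             c90 + 0.05 * stats::rnorm(length(t)))
  im <- imaginary_coherence_matrix(y, fs = 200, window_s = 2, nfft = 400)
  b10 <- which.min(abs(im$freq - 10))
  expect_gt(im$coh[1, 2, b10], 0.9)
  noise <- matrix(stats::rnorm(2 * 12000), ncol = 2)
  imn <- imaginary_coherence_matrix(noise, fs = 200, window_s = 2,
                                    nfft = 400)
  expect_lt(mean(imn$coh[1, 2, ]), 0.15)
})

test_that("band averaging: inclusive bin rule, constants, default order", {
  freq <- seq(0, 50, by = 0.5)
  mats <- lapply(seq_along(freq), function(i) {
    m <- matrix(0.3, 3, 3)
    diag(m) <- 0
    m
  })
  sc <- make_sc(freq, mats)
  bc <- band_average(sc)
  expect_identical(bc$bands, band_scheme()$name)  # delta..gamma order
  for (b in bc$bands)
    expect_true(all(abs(bc$matrices[[b]][upper.tri(diag(3))] - 0.3) <
                      1e-12))
  # gamma 30-45 Hz on the 0.5 grid: 31 bins, both edges included
  expect_equal(sum(freq >= 30 & freq <= 45), 31)
  # mark gamma bins with a distinct value, check the inclusive mean
  mats2 <- mats
  for (i in which(freq >= 30 & freq <= 45))
    mats2[[i]][1, 2] <- mats2[[i]][2, 1] <- 0.9
  expect_equal(band_average(make_sc(freq, mats2))$matrices$gamma[1, 2],
               0.9)
  # empty band errors by name
  expect_error(band_average(make_sc(c(0, 0.5), mats[1:2])), "delta")
})

test_that("epoch averaging is the element-wise mean and commutes", {
  set.seed(46)
  mk <- function(v) {
    m <- matrix(v, 4, 4)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    band_connectome(list(delta = m, theta = m * 0.5))
  }
  e0 <- mk(0)
  e1 <- mk(1)
  avg <- average_epochs(list(e0, e1))
  expect_equal(avg$matrices$delta[1, 2], 0.5)
  expect_equal(average_epochs(list(e1))$matrices$delta,
               e1$matrices$delta)
  expect_equal(average_epochs(list(e1, e1, e1))$matrices$theta,
               e1$matrices$theta)
  expect_error(average_epochs(list()), "no epochs")
  # band averaging commutes with epoch averaging
  freq <- seq(0, 50, by = 0.5)
  rand_sc <- function(seed) {
    set.seed(seed)
    mats <- lapply(seq_along(freq), function(i) {
      m <- matrix(stats::runif(9), 3)
      m <- (m + t(m)) / 2
      diag(m) <- 0
      m
    })
    make_sc(freq, mats)
  }
  s1 <- rand_sc(1)
  s2 <- rand_sc(2)
  path_a <- average_epochs(list(band_average(s1), band_average(s2)))
  mean_sc <- make_sc(freq, lapply(seq_along(freq), function(i)
    (s1$coh[, , i] + s2$coh[, , i]) / 2))
  path_b <- band_average(mean_sc)
  for (b in path_a$bands)
    expect_equal(path_a$matrices[[b]], path_b$matrices[[b]],
                 tolerance = 1e-12)
})
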