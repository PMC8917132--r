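test_that("SWR spike binning conserves counts and sequence length", {
  ev <- event_table(1, 10, 10.03, 10.06)
  sp <- spike_table(rep(c("a", "b"), c(4, 3)), rep("pyr", 7),
                    c(10.001, 10.016, 10.031, 10.046,
                      10.002, 10.017, 10.058))
  bs <- bin_swr_spikes(sp, ev[1, ])
  expect_equal(nrow(bs$counts), 4L)        # ceil(60 / 15)
  expect_equal(sum(bs$counts), 7L)
  expect_equal(bs$counts[, "a"], c(1L, 1L, 1L, 1L))

  none <- bin_swr_spikes(spike_table("a", "pyr", 50), ev[1, ],
                         cell_ids = "a")
  expect_true(all(none$counts == 0L))
})

test_that("forward-backward equals exhaustive path enumeration", {
  for (M in 2:3) {
    for (Tn in c(2, 4, 6)) {
      g <- gen_hmm_counts(n_cells = 4, M = M, T_per_seq = Tn, n_seq = 1,
                          seed = M * 10 + Tn)
      p <- list(pi = g$pi, A = g$A, Lambda = g$Lambda)
      ll_fb <- sequence_loglik(g$sequences[[1]], p) * Tn
      ll_bf <- brute_force_hmm_ll(g$sequences[[1]], g$pi, g$A, g$Lambda)
      expect_equal(ll_fb, ll_bf, tolerance = 1e-10)
    }
  }
})

test_that("single-state fit reduces to independent Poisson closed forms", {
  g <- gen_hmm_counts(5, 1, 6, 20, seed = 2)
  f <- fit_poisson_hmm(g$sequences, M = 1, n_restarts = 1, seed = 3)
  mu <- colMeans(do.call(rbind, g$sequences))
  expect_equal(as.numeric(f$Lambda), as.numeric(mu), tolerance = 1e-9)
  ll_closed <- sum(vapply(g$sequences, function(y) {
    sum(stats::dpois(y, rep(mu, each = nrow(y)), log = TRUE))
  }, numeric(1)))
  expect_equal(f$loglik, ll_closed, tolerance = 1e-8)
  expect_equal(sequence_loglik(g$sequences[[1]], f),
               sum(stats::dpois(g$sequences[[1]],
                                rep(mu, each = 6), log = TRUE)) / 6,
               tolerance = 1e-8)
})

test_that("EM is deterministic under a seed and monotone in likelihood", {
  g <- gen_hmm_counts(6, 3, c(5, 9), 40, seed = 4)
  f1 <- fit_poisson_hmm(g$sequences, M = 3, n_restarts = 2, seed = 5)
  f2 <- fit_poisson_hmm(g$sequences, M = 3, n_restarts = 2, seed = 5)
  expect_identical(f1$Lambda, f2$Lambda)
  expect_identical(f1$A, f2$A)
  expect_true(all(diff(f1$ll_trace) > -1e-8))
  # stochasticity constraints preserved by the M-steps
  expect_equal(sum(f1$pi), 1, tolerance = 1e-8)
  expect_equal(rowSums(f1$A), rep(1, 3), tolerance = 1e-8)
  expect_true(all(f1$Lambda > 0))
})

test_that("log-likelihood is invariant to state relabeling", {
  g <- gen_hmm_counts(5, 3, 8, 5, seed = 6)
  p <- list(pi = g$pi, A = g$A, Lambda = g$Lambda)
  prm <- c(3, 1, 2)
  p2 <- list(pi = g$pi[prm], A = g$A[prm, prm], Lambda = g$Lambda[, prm])
  for (s in 1:5)
    expect_equal(sequence_loglik(g$sequences[[s]], p),
                 sequence_loglik(g$sequences[[s]], p2), tolerance = 1e-12)
})

test_that("EM recovers generating parameters on well-separated data", {
  g <- gen_hmm_counts(10, 3, c(6, 10), 120, seed = 11)
  f <- fit_poisson_hmm(g$sequences, M = 3, n_restarts = 3, seed = 12)
  prm <- match_columns(f$Lambda, g$Lambda)
  rel <- abs(f$Lambda[, prm] - g$Lambda) / pmax(g$Lambda, 1e-9)
  expect_lt(stats::median(rel), 0.15)
  tv <- 0.5 * rowSums(abs(f$A[prm, prm] - g$A))
  expect_true(all(tv < 0.2))
})

test_that("all-zero data fit lands on the rate floor", {
  zero <- replicate(5, matrix(0L, 6, 4), simplify = FALSE)
  f <- fit_poisson_hmm(zero, M = 2, n_restarts = 1, seed = 1)
  expect_true(all(f$Lambda == 1e-4))
  expect_true(is.finite(f$loglik))
})

test_that("cross-quintile comparison separates distinct sequence models", {
  gA <- gen_hmm_counts(8, 3, c(5, 9), 30,
                       param_ranges = list(lambda = c(0.05, 3),
                                           self_bias = 5), seed = 1)
  gB <- gen_hmm_counts(8, 3, c(5, 9), 30,
                       param_ranges = list(lambda = c(0.05, 3),
                                           self_bias = 0), seed = 2)
  r <- cross_quintile_hmm_test(gA$sequences, gB$sequences, M = 3,
                               n_shuffles = 20, seed = 3,
                               n_restarts = 1, tol = 1e-4)
  expect_true(all(r$observed < 0))
  expect_lt(max(r$p_values), 0.1)

  # degenerate identity: testing the training set gives difference 0
  f <- fit_poisson_hmm(gA$sequences, M = 2, n_restarts = 1, seed = 9)
  ll <- vapply(gA$sequences, sequence_loglik, numeric(1), params = f)
  expect_equal(mean(ll) - mean(ll), 0)

  expect_true(cross_quintile_hmm_test(gA$sequences[1],
                                      gB$sequences, M = 2)$skipped)
})

test_that("twofold state-count selection returns a grid value", {
  g <- gen_hmm_counts(6, 2, c(5, 8), 40, seed = 21)
  cv <- cv_select_states(g$sequences, M_grid = c(1, 2, 4), seed = 22,
                         n_restarts = 1, tol = 1e-4)
  expect_true(cv$M_star %in% c(1, 2, 4))
  expect_length(cv$cv_loglik, 3L)
  expect_true(all(is.finite(cv$cv_loglik)))
})
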