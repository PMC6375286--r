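test_that("subsampling a lineage with equal leaf times is degenerate", {
  tab <- toy_tree_table()
  rts <- toy_response_set(leaf_values = rep(2.5, 4))
  s <- subsample_trajectories(tab, rts, stats_config(n_subsamples = 20,
                                                     seed = 1))
  expect_true(all(s$times$yfp == 2.5))
  expect_equal(dim(s$times$yfp), c(1, 20))
})

test_that("each division branch is chosen uniformly", {
  tab <- toy_tree_table()
  rts <- toy_response_set(leaf_values = c(1, 2, 3, 4))
  s <- subsample_trajectories(tab, rts, stats_config(n_subsamples = 4000,
                                                     seed = 2))
  freq <- table(factor(s$times$yfp, levels = 1:4)) / 4000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("subsampling is reproducible under a fixed seed", {
  tab <- toy_tree_table()
  rts <- toy_response_set()
  cfg <- stats_config(n_subsamples = 50, seed = 7)
  expect_identical(subsample_trajectories(tab, rts, cfg),
                   subsample_trajectories(tab, rts, cfg))
  expect_error(subsample_trajectories(
    tab, transform(rts, founder_id = NA), cfg), "founder")
})

test_that("timing summary collapses correctly in degenerate cases", {
  m <- matrix(3, nrow = 5, ncol = 10)
  ts <- timing_summary(m, config = stats_config(n_bootstrap = 50, seed = 1))
  expect_equal(ts$mu_t, 3)
  expect_equal(ts$sigma_t, 0)
  expect_equal(ts$se_sigma, 0)
  # S = 1 reduces to the plain mean/sd of the single sample
  x <- c(1, 2, 4, 8)
  ts1 <- timing_summary(matrix(x, ncol = 1),
                        config = stats_config(n_bootstrap = 50, seed = 1))
  expect_equal(ts1$mu_t, mean(x))
  expect_equal(ts1$sigma_t, sd(x))
  expect_error(timing_summary(matrix(1, 1, 3)), "2 founders")
})

test_that("timing summary recovers the Erlang generator's mean within its error", {
  x <- sample_erlang(chain_spec(37, 1.87), 50, seed = 3)
  m <- matrix(x, nrow = 50, ncol = 40)   # one trajectory per founder
  ts <- timing_summary(m, config = stats_config(n_bootstrap = 500, seed = 4))
  expect_equal(ts$mu_t, mean(x))         # path trees reduce to the plain mean
  expect_lt(abs(ts$mu_t - 1.87), 3 * ts$se_mu)
})

test_that("bootstrap errors shrink with founder count", {
  big <- matrix(sample_erlang(chain_spec(8, 4), 200, seed = 5), ncol = 1)
  small <- big[1:20, , drop = FALSE]
  cfg <- stats_config(n_bootstrap = 300, seed = 6)
  expect_lt(timing_summary(big, config = cfg)$se_mu,
            timing_summary(small, config = cfg)$se_mu)
})

test_that("paired correlation handles perfect, absent and tuned dependence", {
  a <- sample_erlang(chain_spec(4, 3), 50, seed = 11)
  perfect <- paired_correlation(constant_samples(a, a))
  expect_equal(perfect$r_mean, 1)

  b <- sample_erlang(chain_spec(4, 3), 50, seed = 12)
  indep <- paired_correlation(constant_samples(a, b))
  expect_lt(abs(indep$r_mean), 0.3)
  expect_gt(indep$p_median, 0.05)

  # serial chains with sd_shared = 0.74 and sd_mid = sqrt(1 - 0.74^2):
  # corr(t_a, t_b) = 0.74 analytically
  spec <- dual_chain_spec("serial",
                          shared = chain_spec(4, 2 * 0.74),
                          mid = chain_spec(1, sqrt(1 - 0.74^2)))
  p <- sample_dual_times(spec, 30, seed = 13)
  pc <- paired_correlation(constant_samples(p$t_a, p$t_b))
  # identical subsamples: the average equals the direct Pearson oracle
  expect_equal(pc$r_mean, cor(p$t_a, p$t_b))
  expect_equal(pc$r_mean, 0.74, tolerance = 3 * (1 - 0.74^2) / sqrt(27))
})

test_that("r_mean is invariant under common affine transforms of both channels", {
  p <- sample_dual_times(
    dual_chain_spec("serial", shared = chain_spec(4, 2),
                    mid = chain_spec(2, 1)), 40, seed = 14)
  r0 <- paired_correlation(constant_samples(p$t_a, p$t_b))$r_mean
  r1 <- paired_correlation(constant_samples(2 * p$t_a + 5,
                                            2 * p$t_b + 5))$r_mean
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("zero-variance subsamples are skipped with a warning", {
  a <- matrix(rep(1, 30), nrow = 3)
  b <- matrix(rnorm(30), nrow = 3)
  expect_warning(expect_error(paired_correlation(list(a, b)), "no usable"),
                 "skipped")
})

test_that("strict-order enumeration matches hand-computed cases", {
  cfg <- stats_config(n_permutations = 100, seed = 21)
  # disjoint supports: every pairing is equally strict, P = 1
  so <- strict_order_test(constant_samples(c(1, 2, 3), c(10, 11, 12), S = 5),
                          cfg)
  expect_equal(so$permutation_P, 1)
  expect_equal(so$order_statistic, 3)
  # A = (1,3), B = (2,4): of the 2 pairings only the observed is fully
  # ordered, P = 1/2
  so2 <- strict_order_test(constant_samples(c(1, 3), c(2, 4), S = 5), cfg)
  expect_equal(so2$permutation_P, 0.5)
})

test_that("Monte-Carlo permutation converges to exact enumeration", {
  # interleaved pairs so the order statistic is informative
  set.seed(30)
  a <- c(1.0, 2.2, 3.1, 4.7, 5.2, 6.9)
  b <- c(1.8, 2.0, 4.4, 4.1, 6.6, 7.3)
  n_perm <- 2000
  exact <- strict_order_test(constant_samples(a, b, S = 1),
                             stats_config(n_permutations = 10, seed = 1))
  mc <- strict_order_test(constant_samples(a, b, S = 1),
                          stats_config(n_permutations = n_perm, seed = 2),
                          exact_limit = 0)
  p <- exact$permutation_P
  expect_lt(abs(mc$permutation_P - p), 3 * sqrt(p * (1 - p) / n_perm))
})

test_that("ties count as non-ordered in the strict-order statistic", {
  so <- strict_order_test(constant_samples(c(1, 2), c(1, 3), S = 2),
                          stats_config(seed = 3))
  expect_equal(so$order_statistic, 1)
})
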