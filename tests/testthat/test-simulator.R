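test_that("degenerate settings reproduce the block fixture exactly", {
  sim <- simulate_block_matrix(2, 2, 0, p_in = 1, noise_ratio = 0, seed = 99)
  expect_identical(sim$matrix$values, m4_matrix()$values)
  expect_equal(sim$truth$cluster_sizes, c(2L, 2L))
  expect_equal(sim$truth$boundaries, c(2L, 4L))
})

test_that("simulation is deterministic per seed and validates parameters", {
  a <- simulate_block_matrix(3, 10, 1, 0.5, 0.2, seed = 7)
  b <- simulate_block_matrix(3, 10, 1, 0.5, 0.2, seed = 7)
  expect_identical(a$matrix$values, b$matrix$values)
  c <- simulate_block_matrix(3, 10, 1, 0.5, 0.2, seed = 8)
  expect_false(identical(a$matrix$values, c$matrix$values))

  expect_error(simulate_block_matrix(3, 10, 0, p_in = 0), "p_in")
  expect_error(simulate_block_matrix(3, 10, 0, noise_ratio = 2),
               "noise_ratio")
  expect_error(simulate_block_matrix(3, 10, -1), "size_sd")
})

test_that("edge frequencies match the stated probabilities", {
  sim <- simulate_block_matrix(4, 30, 0, p_in = 0.5, noise_ratio = 0.2,
                               seed = 123)
  x <- sim$matrix$values
  member <- rep(seq_along(sim$truth$cluster_sizes), sim$truth$cluster_sizes)
  same <- outer(member, member, "==") & upper.tri(x)
  diff_c <- !outer(member, member, "==") & upper.tri(x)
  p_intra <- mean(x[same])
  p_inter <- mean(x[diff_c])
  # binomial tolerance: ~4 sd of the empirical proportions
  expect_lt(abs(p_intra - 0.5), 4 * sqrt(0.25 / sum(same)))
  expect_lt(abs(p_inter - 0.1), 4 * sqrt(0.09 / sum(diff_c)))
})

test_that("cluster sizes follow the rounded, clipped Gaussian scheme", {
  sim <- simulate_block_matrix(6, 10, 3, p_in = 0.5, noise_ratio = 0.1,
                               seed = 17)
  expect_true(all(sim$truth$cluster_sizes >= 2L))
  expect_equal(sum(sim$truth$cluster_sizes), sim$matrix$n)
  expect_equal(sim$truth$boundaries, cumsum(sim$truth$cluster_sizes))
  # sd = 0 gives exactly equal sizes
  eq <- simulate_block_matrix(5, 9, 0, seed = 2)
  expect_equal(eq$truth$cluster_sizes, rep(9L, 5))
})

test_that("noiseless planted structure is recovered perfectly", {
  res <- recovery_experiment(3, 6, 0, p_in = 1, noise_ratios = 0, reps = 3,
                             seed = 5)
  expect_equal(res$results$overlapping_ratio, rep(1, 3))
  expect_equal(res$results$weighted_similarity, rep(1, 3))
  expect_equal(nrow(res$results), 3L)  # |noise_ratios| x reps rows
})

test_that("recovery degrades with the noise ratio on average", {
  res <- recovery_experiment(4, 6, 0, 0.5, noise_ratios = c(0.1, 0.6),
                             reps = 6, seed = 13)
  expect_equal(nrow(res$results), 12L)
  s <- res$summary
  expect_gte(s$median_or[s$noise_ratio == 0.1],
             s$median_or[s$noise_ratio == 0.6])
})
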