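test_that("inherent density deducts ancestor layers top-down", {
  # uniform off-diagonal matrix: all pair means are 1, children inherit 0
  ones <- matrix(1, 4, 4); diag(ones) <- 0
  P1 <- prefix_sums(contact_matrix(ones))
  tr <- partition_tree(c(2, 4), 4)
  inh <- inherent_density(P1, tr)
  expect_equal(inh[1], 1)       # root: mean over cross pairs
  expect_equal(inh[2], 0)       # child: 1 - 1
  expect_equal(inh[3], 0)

  # block fixture: cross pairs are 0, blocks are pure signal
  P <- m4_prefix()
  inh <- inherent_density(P, tr)
  expect_equal(inh[1], 0)
  expect_equal(inh[2], 1)
  expect_equal(inh[3], 1)

  # single-bin leaves have no pairs
  tr1 <- partition_tree(c(1, 4), 4)
  expect_equal(inherent_density(P, tr1)[2], 0)
})

test_that("clustering scores are degenerate-safe, separating, deterministic", {
  # identical feature vectors: nothing to split, everyone selected
  f0 <- data.frame(id = 1:4, size = 5, inherent_density = 1,
                   entropy = 0, parent_entropy = 0)
  expect_equal(cluster_and_score(f0, restarts = 10, seed = 1)$selection_probability,
               rep(1, 4))

  # two well-separated groups: small/dense selected, large/sparse not
  f <- data.frame(id = 1:8,
                  size = c(3, 4, 3, 4, 40, 42, 41, 39),
                  inherent_density = c(9, 8.5, 9.2, 8.8, 0.3, 0.25, 0.32, 0.2))
  f$entropy <- 0; f$parent_entropy <- 0
  sc <- cluster_and_score(f, restarts = 50, seed = 2)
  expect_equal(sc$selection_probability[1:4], rep(1, 4))
  expect_equal(sc$selection_probability[5:8], rep(0, 4))

  # identical seeds give identical probabilities
  sc2 <- cluster_and_score(f, restarts = 50, seed = 2)
  expect_identical(sc$selection_probability, sc2$selection_probability)
  expect_error(cluster_and_score(f, restarts = 0), "restarts")
})

test_that("pruning is a conjunction and never touches the root or intervals", {
  sim <- simulate_block_matrix(3, 6, 0, p_in = 1, noise_ratio = 0, seed = 5)
  P <- prefix_sums(sim$matrix)
  fit <- select_k(P)
  feats <- node_features(P, fit$tree)

  # high probability keeps a node regardless of the other two conditions
  feats$selection_probability <- 0.9
  rec <- prune_domains(P, fit$tree, feats)
  expect_true(all(rec$kept))

  # low probability alone is not enough unless entropy and split agree
  feats$selection_probability <- 0.1
  rec2 <- prune_domains(P, fit$tree, feats)
  manual <- with(feats, {
    nd <- fit$tree$nodes
    psz <- nd$end[id] - nd$start[id] + 1
    par <- nd$parent[id]
    parsz <- nd$end[par] - nd$start[par] + 1
    !(entropy < parent_entropy & abs(psz - parsz / 2) <= 0.1 * parsz)
  })
  expect_equal(rec2$kept[match(feats$id, rec2$id)], manual)

  # records are the unfiltered table with only the kept flag changed
  base <- domain_records(P, fit$tree)
  expect_identical(rec2[, c("id", "level", "start_bin", "end_bin",
                            "entropy", "density")],
                   base[, c("id", "level", "start_bin", "end_bin",
                            "entropy", "density")])
  expect_false(any(is.na(rec2$kept)))
  # the root is never a domain record
  root_id <- fit$tree$nodes$id[is.na(fit$tree$nodes$parent)]
  expect_false(root_id %in% rec2$id)
  expect_error(prune_domains(P, fit$tree, feats, prob_threshold = 1.5),
               "prob_threshold")
})

test_that("planted-block domains survive filtering at moderate noise", {
  sim <- simulate_block_matrix(4, 8, 0, p_in = 0.5, noise_ratio = 0.10,
                               seed = 21)
  det <- detect_tads(sim$matrix, filter = TRUE, restarts = 200,
                     filter_seed = 3)
  kept <- det$records[det$records$kept, ]
  truth <- sim$truth$partition
  for (i in seq_along(truth$start)) {
    expect_true(any(kept$start_bin == truth$start[i] &
                    kept$end_bin == truth$end[i]))
  }
})
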