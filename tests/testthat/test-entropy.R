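test_that("prefix sums, volume and cut match direct summation on fixtures", {
  P <- m4_prefix()
  expect_equal(P$two_m, 4)
  expect_equal(P$row_sum, rep(1, 4))

  expect_equal(volume(P, c(1, 2)), 2)
  expect_equal(volume(P, c(1, 4)), 4)   # V(root) = 2m
  expect_equal(volume(P, c(1, 1)), 1)

  expect_equal(cut_weight(P, c(1, 2)), 0)
  expect_equal(cut_weight(P, c(1, 1)), 1)  # single bin: g = V
  expect_equal(cut_weight(P, c(1, 4)), 0)  # nothing outside the root

  expect_error(volume(P, c(3, 2)), "invalid")
  expect_error(volume(P, c(0, 2)), "invalid")

  # all-zero matrix is degenerate
  expect_error(prefix_sums(contact_matrix(matrix(0, 3, 3))), "degenerate")
})

test_that("volume and cut agree with double-loop summation on random data", {
  for (seed in 1:4) {
    x <- rand_sym_counts(20, seed = seed)
    P <- prefix_sums(contact_matrix(x))
    ivs <- withr::with_seed(100 + seed, {
      s <- sample(20, 50, replace = TRUE)
      e <- pmin(20, s + sample(0:19, 50, replace = TRUE))
      cbind(s, e)
    })
    for (r in seq_len(nrow(ivs))) {
      iv <- ivs[r, ]
      inside <- iv[1]:iv[2]
      expect_equal(volume(P, iv), sum(x[inside, ]))
      expect_equal(cut_weight(P, iv), sum(x[inside, setdiff(1:20, inside)]))
    }
  }
})

test_that("node and bin entropy terms follow the defining formula", {
  P <- m4_prefix()
  expect_equal(node_entropy(P, c(1, 1), c(1, 2)), 0.25)  # -(1/4)log2(1/2)
  expect_equal(node_entropy(P, c(1, 2), c(1, 4)), 0)     # g = 0
  expect_equal(node_entropy(P, c(1, 2), c(1, 2)), 0)     # child == parent
  expect_error(node_entropy(P, c(1, 3), c(2, 4)), "contained")

  expect_equal(leaf_bin_entropy(P, c(1, 2)), 0.5)
  expect_equal(leaf_bin_entropy(P, c(1, 1)), 0)          # V(b) = V(leaf)
  expect_equal(leaf_bin_entropy(P, c(1, 4)), 2.0)
})

test_that("tree entropy sums node and bin terms with a zero root term", {
  P <- m4_prefix()
  expect_equal(tree_entropy(P, partition_tree(c(2, 4), 4)), 1.0)
  expect_equal(tree_entropy(P, partition_tree(4, 4)), 2.0)  # root-only
  nested <- coding_tree(data.frame(parent = c(NA, 1, 1, 2, 2),
                                   start = c(1, 1, 3, 1, 2),
                                   end = c(4, 2, 4, 1, 2)), 4)
  expect_equal(tree_entropy(P, nested), 1.0)  # 0.25 + 0.25 + bins of [3,4]
})

test_that("volume is exactly additive and cut superadditive over children", {
  # Lemma-style check on random partitions of random intervals
  for (seed in 1:5) {
    x <- rand_sym_counts(15, seed = seed)
    P <- prefix_sums(contact_matrix(x))
    withr::with_seed(200 + seed, {
      for (rep in 1:20) {
        a <- sample(15, 1)
        b <- sample(a:15, 1)
        len <- b - a + 1
        if (len < 2) next
        ncut <- sample(seq_len(len - 1), 1)
        cuts <- sort(sample(seq_len(len - 1), ncut))
        ends <- c(a - 1 + cuts, b)
        starts <- c(a, ends[-length(ends)] + 1)
        vs <- mapply(function(s, e) volume(P, c(s, e)), starts, ends)
        gs <- mapply(function(s, e) cut_weight(P, c(s, e)), starts, ends)
        expect_identical(sum(vs), volume(P, c(a, b)))
        expect_gte(sum(gs), cut_weight(P, c(a, b)) - 1e-9)
      }
    })
  }
})

test_that("contact density counts each intra pair once per bin", {
  P <- m4_prefix()
  expect_equal(contact_density(P, c(1, 2)), 0.5)
  expect_equal(contact_density(P, c(2, 3)), 0)
  expect_equal(contact_density(P, c(1, 4)), 0.5)
})

test_that("entropy terms are non-negative on random inputs", {
  for (seed in 1:3) {
    x <- rand_sym_counts(10, seed = seed)
    P <- prefix_sums(contact_matrix(x))
    withr::with_seed(300 + seed, {
      pick <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
      for (rep in 1:30) {
        ps <- pick(1, 10); pe <- pick(ps, 10)
        cs <- pick(ps, pe); ce <- pick(cs, pe)
        expect_gte(node_entropy(P, c(cs, ce), c(ps, pe)), 0)
        expect_gte(leaf_bin_entropy(P, c(cs, ce)), 0)
      }
    })
  }
})
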