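test_that("interval overlap counts shared bins", {
  expect_equal(interval_overlap(c(1, 4), c(4, 8)), 1L)
  expect_equal(interval_overlap(c(1, 4), c(5, 8)), 0L)
  expect_equal(interval_overlap(c(1, 4), c(1, 4)), 4L)
})

test_that("overlapping ratio matches the worked matching by hand", {
  wp <- worked_pair()
  # best matching pairs [1,4]~[1,3] (3) and [5,8]~[4,8] (4): 2*7/16
  expect_equal(overlapping_ratio(wp$X, wp$Y), 0.875)
  expect_equal(overlapping_ratio(wp$X, wp$X), 1)
  A <- tad_partition(data.frame(start = 1, end = 4), 8)
  B <- tad_partition(data.frame(start = 5, end = 8), 8)
  expect_equal(overlapping_ratio(A, B), 0)
  C <- tad_partition(data.frame(start = 1, end = 4), 9)
  expect_error(overlapping_ratio(A, C), "different bin counts")
})

test_that("weighted similarity matches the worked value and is asymmetric", {
  wp <- worked_pair()
  expected <- (3 * 3 / sqrt(12) + 5 * 4 / sqrt(20)) / 8  # 0.8837765...
  expect_equal(weighted_similarity(wp$X, wp$Y), expected, tolerance = 1e-12)
  expect_equal(round(expected, 7), 0.8837765)
  expect_equal(weighted_similarity(wp$X, wp$X), 1)
  A <- tad_partition(data.frame(start = 1, end = 4), 8)
  B <- tad_partition(data.frame(start = 5, end = 8), 8)
  expect_equal(weighted_similarity(A, B), 0)
})

test_that("measure of concordance matches hand evaluation on tilings", {
  wp <- worked_pair()
  # (1/(sqrt(4)-1)) * (9/12 + 1/20 + 0 + 16/20 - 1)
  expect_equal(moc(wp$X, wp$Y), 0.6)
  expect_equal(moc(wp$X, wp$X), 1)
  one <- tad_partition(data.frame(start = 1, end = 8), 8)
  expect_equal(moc(one, one), 1)  # N_X = N_Y = 1 convention
  gappy <- tad_partition(data.frame(start = c(1, 6), end = c(3, 8)), 8)
  expect_error(moc(gappy, wp$X), "tile")
  filled <- fill_partition_gaps(gappy)
  expect_equal(sum(filled$end - filled$start + 1), 8L)
  expect_equal(moc(filled, filled), 1)
})

test_that("matching-based metrics are symmetric and bounded on random pairs", {
  withr::with_seed(31, {
    for (rep in 1:30) {
      n <- sample(8:20, 1)
      rand_part <- function() {
        ends <- sort(sample(n, sample(1:min(6, n), 1)))
        ends[length(ends)] <- n
        ends <- unique(ends)
        tad_partition(data.frame(start = c(1, head(ends, -1) + 1),
                                 end = ends), n)
      }
      X <- rand_part(); Y <- rand_part()
      or_xy <- overlapping_ratio(X, Y)
      expect_gte(or_xy, 0); expect_lte(or_xy, 1)
      expect_equal(or_xy, overlapping_ratio(Y, X))
      expect_equal(moc(X, Y), moc(Y, X))
      m <- moc(X, Y)
      expect_gte(m, -1e-12); expect_lte(m, 1 + 1e-12)
    }
  })
})

test_that("the matching solver is exact against exhaustive enumeration", {
  withr::with_seed(57, {
    for (rep in 1:20) {
      w <- matrix(sample(0:6, 5 * 6, replace = TRUE), 5, 6)
      expect_equal(entroTAD:::max_matching_weight(w),
                   brute_matching_weight(w))
    }
  })
})

test_that("tree flattening exposes leaf or all-node interval sets", {
  tr <- coding_tree(data.frame(parent = c(NA, 1, 1, 3, 3),
                               start = c(1, 1, 3, 3, 4),
                               end = c(4, 2, 4, 3, 4)), 4)
  lv <- partition_from_tree(tr)
  expect_equal(lv$start, c(1L, 3L, 4L))
  all_iv <- partition_from_tree(tr, nodes = "all")
  expect_equal(length(all_iv$start), 4L)  # every non-root node
})
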