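test_that("dense matrices are read, validated and diagonal-zeroed", {
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines(c("0 1", "1 0"), f)
  M <- read_dense_matrix(f)
  expect_equal(M$n, 2L)
  expect_equal(M$values[1, 2], 1)

  # nonzero diagonal is zeroed with a warning
  writeLines(c("5 1", "1 5"), f)
  expect_warning(M <- read_dense_matrix(f), "diagonal")
  expect_equal(diag(M$values), c(0, 0))
  expect_equal(M$values[1, 2], 1)

  writeLines(c("0 1 2", "1 0"), f)
  expect_error(read_dense_matrix(f), "ragged")

  writeLines(c("0 1 2", "1 0 1", "2 1 0", "0 0 0"), f)
  expect_error(read_dense_matrix(f), "square")

  writeLines(c("0 -1", "-1 0"), f)
  expect_error(read_dense_matrix(f), "negative")

  writeLines(c("0 a", "a 0"), f)
  expect_error(read_dense_matrix(f), "non-numeric")

  writeLines(c("0 1", "9 0"), f)
  expect_error(read_dense_matrix(f), "asymmetric")

  expect_error(read_dense_matrix(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("dense write/read round-trips values", {
  f <- withr::local_tempfile(fileext = ".txt")
  x <- rand_sym_counts(12, seed = 5) / 3  # non-integer values too
  M <- contact_matrix(x)
  write_dense_matrix(M, f)
  M2 <- read_dense_matrix(f)
  expect_equal(M2$values, M$values, tolerance = 1e-12)
})

test_that("sparse triplets build symmetric matrices and catch bad input", {
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines("1 2 3.0", f)
  M <- read_sparse_triplets(f, n = 3)
  expect_equal(M$values[1, 2], 3)
  expect_equal(M$values[2, 1], 3)
  expect_equal(sum(M$values), 6)

  # 0-based dialect
  writeLines("0 1 3.0", f)
  M0 <- read_sparse_triplets(f, n = 3, one_based = FALSE)
  expect_equal(M0$values, M$values)

  writeLines(c("1 2 3.0", "2 1 4.0"), f)
  expect_error(read_sparse_triplets(f, n = 3), "conflicting")

  writeLines("4 1 1.0", f)
  expect_error(read_sparse_triplets(f, n = 3), "out of range")
})

test_that("sparse upper triangle reproduces any valid matrix exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  for (seed in 1:3) {
    x <- rand_sym_counts(9, seed = seed)
    idx <- which(upper.tri(x) & x > 0, arr.ind = TRUE)
    writeLines(sprintf("%d %d %g", idx[, 1], idx[, 2], x[idx]), f)
    M <- read_sparse_triplets(f, n = 9)
    expect_identical(M$values, x + 0)  # numeric copy of the source counts
  }
})

test_that("domain TSVs carry genomic coordinates and deterministic order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  P <- m4_prefix()
  tree <- coding_tree(data.frame(parent = c(NA, 1, 1, 3, 3),
                                 start = c(1, 1, 3, 3, 4),
                                 end = c(4, 2, 4, 3, 4)), 4)
  rec <- domain_records(P, tree)
  write_domains(rec, f, resolution = 25000, chrom = "chr6")
  tab <- read_domains(f)
  # parents precede children; level-1 rows first
  expect_equal(tab$level, c(1, 1, 2, 2))
  # bp arithmetic: start_bp = (start_bin - 1) * resolution
  expect_equal(tab$start_bp[1], 0)
  expect_equal(tab$end_bp[1], 50000)
  expect_equal(tab$chrom[1], "chr6")

  # empty record set -> header only
  write_domains(rec[0, ], f)
  expect_equal(nrow(read_domains(f)), 0L)
  expect_true(grepl("level", readLines(f)[1]))
})

test_that("leaf partitions are recovered from record tables", {
  P <- m4_prefix()
  tree <- coding_tree(data.frame(parent = c(NA, 1, 1, 3, 3),
                                 start = c(1, 1, 3, 3, 4),
                                 end = c(4, 2, 4, 3, 4)), 4)
  part <- domains_to_partition(domain_records(P, tree), 4)
  expect_equal(part$start, c(1L, 3L, 4L))
  expect_equal(part$end, c(2L, 3L, 4L))
})
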