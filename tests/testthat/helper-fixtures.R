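# Shared fixtures and independent oracles, all built in code.

# two 2-bin blocks: x[1,2] = x[3,4] = 1, zero elsewhere; 2m = 4
m4_matrix <- function() {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1
  contact_matrix(m)
}
m4_prefix <- function() prefix_sums(m4_matrix())

# random symmetric integer-count matrix with zero diagonal and positive total
rand_sym_counts <- function(n, seed, lambda = 2) {
  withr::with_seed(seed, {
    repeat {
      x <- matrix(stats::rpois(n * n, lambda), n)
      x <- x + t(x)
      diag(x) <- 0
      if (sum(x) > 0) break
    }
    x
  })
}

# the worked 8-bin partition pair: X = {[1,4],[5,8]}, Y = {[1,3],[4,8]}
worked_pair <- function() {
  list(X = tad_partition(data.frame(start = c(1, 5), end = c(4, 8)), 8),
       Y = tad_partition(data.frame(start = c(1, 4), end = c(3, 8)), 8))
}

# random ordered multi-nary coding tree over n bins (node table with >= 2
# children per internal node); split_prob controls expected depth
rand_multinary_nodes <- function(n, seed, split_prob = 0.7) {
  withr::with_seed(seed, {
    build <- function(a, b) {
      if (b == a || stats::runif(1) > split_prob)
        return(data.frame(parent = NA_integer_, start = a, end = b))
      len <- b - a + 1L
      cand <- seq(2L, min(len, 4L))
      nparts <- cand[sample.int(length(cand), 1L)]
      cuts <- sort(sample(seq_len(len - 1L), nparts - 1L))
      ends <- c(a - 1L + cuts, b)
      starts <- c(a, ends[-length(ends)] + 1L)
      nodes <- data.frame(parent = NA_integer_, start = a, end = b)
      for (j in seq_along(starts)) {
        child <- build(starts[j], ends[j])
        off <- nrow(nodes)
        child$parent <- child$parent + off
        child$parent[1L] <- 1L
        nodes <- rbind(nodes, child)
      }
      nodes
    }
    build(1L, as.integer(n))
  })
}

# merge children 2..l of a >= 3-ary node under a fresh intermediate node
# (the binarizing transformation); returns NULL when no such node exists
binarize_one_node <- function(nodes) {
  for (v in seq_len(nrow(nodes))) {
    kids <- which(!is.na(nodes$parent) & nodes$parent == v)
    if (length(kids) < 3L) next
    kids <- kids[order(nodes$start[kids])]
    grouped <- kids[-1L]
    u <- nrow(nodes) + 1L
    nodes <- rbind(nodes,
                   data.frame(parent = v,
                              start = min(nodes$start[grouped]),
                              end = max(nodes$end[grouped])))
    nodes$parent[grouped] <- u
    return(nodes)
  }
  NULL
}

# exhaustive maximum-weight matching value over all bipartite matchings
# (independent oracle for the assignment solver); feasible for <= ~7 x 7
brute_matching_weight <- function(w) {
  nx <- nrow(w); ny <- ncol(w)
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > nx) { best <<- max(best, acc); return(invisible()) }
    recurse(i + 1L, used, acc)          # leave row i unmatched
    for (j in seq_len(ny)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + w[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ny), 0)
  best
}

cli_script <- function() {
  p <- system.file("exec", "entrotad.R", package = "entroTAD")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(args) {
  out <- suppressWarnings(system2("Rscript", c(cli_script(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
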