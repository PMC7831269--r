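#' Optimal multi-nary coding tree of bounded height
#'
#' Exact dynamic program for the minimal-entropy coding tree of height at
#' most \code{h} (root at height 0; \code{h = 1} is a root plus one level of
#' leaf children, \code{h = 2} a two-level hierarchy) with at most
#' \code{k_max} leaves. Nodes may have any number of children (at least two).
#' The recurrence peels children off a node right-to-left: the state
#' \eqn{T(l:r, p, k, h)} holds the minimal entropy of the children of node
#' \eqn{[l..r]} tiling \eqn{[l..p]} with \eqn{k} leaves; the last child
#' \eqn{[i+1..p]} contributes its node term plus its own subtree at height
#' budget \eqn{h - 1}, and the remainder \eqn{[l..i]} either continues
#' peeling or closes as a single child. A node kept as a leaf contributes its
#' bin-level terms; an exhausted height budget forces a leaf. Cost
#' O(n^4 k^2 h), so this mode is intended for moderate matrix sizes.
#'
#' Because entropy is non-increasing in the number of leaves, the tree
#' returned is the best over all leaf counts up to \code{k_max} (ties go to
#' the smallest leaf count).
#'
#' @param P a \code{\link{prefix_sums}} object.
#' @param h maximum tree height, \code{>= 1}.
#' @param k_max maximum number of leaves, \code{1 <= k_max <= n}.
#' @param boundaries optional integer vector of allowed split positions
#'   (a split after bin \code{i} separates bins \code{i} and \code{i + 1}),
#'   e.g. from \code{\link{candidate_boundaries}}; \code{NULL} (default)
#'   allows every position. Restricting splits is an optional acceleration
#'   and changes the search space.
#' @return list with \code{tree}, \code{entropy}, \code{k} (leaf count of
#'   the returned tree) and \code{entropy_by_k} (optimal entropy for each
#'   exact leaf count up to \code{k_max}).
#' @export
optimal_tree_height <- function(P, h, k_max, boundaries = NULL) {
  stopifnot(inherits(P, "prefix_sums"))
  h <- as.integer(h)
  k_max <- as.integer(k_max)
  if (is.na(h) || h < 1L) stop("'h' must be >= 1", call. = FALSE)
  if (is.na(k_max) || k_max < 1L || k_max > P$n)
    stop("'k_max' must be in [1, n]", call. = FALSE)
  splits <- if (is.null(boundaries)) integer(0) else as.integer(boundaries)
  res <- .dp_multinary_cpp(P$row_cum, P$rect, P$two_m, k_max, h, splits)
  list(tree = tree_from_cpp(res$nodes, P$n), entropy = res$entropy,
       k = res$k, entropy_by_k = res$entropy_by_k)
}

# all ordered multi-nary trees over [a..b] with height <= h (local root at
# height 0), every internal node having >= 2 children
enumerate_multinary <- function(a, b, h) {
  leaf <- list(data.frame(parent = NA_integer_, start = a, end = b))
  if (h == 0L || b == a) return(leaf)
  out <- leaf
  for (comp in compositions_of(b - a + 1L)) {
    ends <- a - 1L + cumsum(comp)
    starts <- c(a, ends[-length(ends)] + 1L)
    sub <- vector("list", length(comp))
    for (j in seq_along(comp))
      sub[[j]] <- enumerate_multinary(starts[j], ends[j], h - 1L)
    for (pick in expand_picks(lengths(sub))) {
      nodes <- data.frame(parent = NA_integer_, start = a, end = b)
      for (j in seq_along(comp)) {
        child <- sub[[j]][[pick[j]]]
        off <- nrow(nodes)
        child$parent <- child$parent + off
        child$parent[1L] <- 1L
        nodes <- rbind(nodes, child)
      }
      out[[length(out) + 1L]] <- nodes
    }
  }
  out
}

# ordered compositions of m into >= 2 positive parts
compositions_of <- function(m) {
  out <- list()
  recurse <- function(rest, acc) {
    if (rest == 0L) {
      if (length(acc) >= 2L) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (first in seq_len(rest)) recurse(rest - first, c(acc, first))
  }
  recurse(m, integer(0))
  out
}

# all index combinations over choice-list lengths (like expand.grid rows)
expand_picks <- function(lens) {
  grid <- do.call(expand.grid, lapply(lens, seq_len))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

#' Brute-force optimal height-bounded tree (independent test oracle)
#'
#' Exhaustively enumerates every ordered multi-nary coding tree with height
#' at most \code{h} and at most \code{k_max} leaves, scoring each with
#' \code{\link{tree_entropy}}. Refuses \code{n > 8}.
#'
#' @inheritParams optimal_tree_height
#' @return list with \code{tree} and \code{entropy}.
#' @export
brute_force_height <- function(P, h, k_max) {
  stopifnot(inherits(P, "prefix_sums"))
  if (P$n > 8L)
    stop("brute-force enumeration refused for n > 8", call. = FALSE)
  h <- as.integer(h)
  k_max <- as.integer(k_max)
  stopifnot(h >= 1L, k_max >= 1L, k_max <= P$n)
  best <- NULL
  best_e <- Inf
  for (nd in enumerate_multinary(1L, P$n, h)) {
    tr <- coding_tree(nd, P$n)
    if (nrow(tree_leaves(tr)) > k_max) next
    e <- tree_entropy(P, tr)
    if (e < best_e - 1e-12) {
      best_e <- e
      best <- tr
    }
  }
  list(tree = best, entropy = best_e)
}

#' Candidate TAD boundaries from the binary DP
#'
#' Boundary positions (splits after a bin) of the optimal binary tree with
#' \code{k_cand} leaves. Passing these to \code{\link{optimal_tree_height}}
#' restricts its split points to this set, trading exactness for speed.
#'
#' @inheritParams optimal_binary_tree
#' @param k_cand leaf count of the binary tree supplying the boundaries.
#' @return increasing integer vector of split positions (empty for
#'   \code{k_cand = 1}).
#' @export
candidate_boundaries <- function(P, k_cand) {
  fit <- optimal_binary_tree(P, k_cand)
  ends <- tree_leaves(fit$tree)$end
  ends[-length(ends)]
}
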