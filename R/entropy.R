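#' Precompute prefix sums for O(1) interval volume and cut queries
#'
#' Structural entropy evaluation repeatedly needs, for arbitrary bin
#' intervals, the volume \eqn{V(u) = \sum_{i \in u, j} x_{ij}} (all weight
#' incident to the interval) and the cut \eqn{g(u) = \sum_{i \in u, j \notin
#' u} x_{ij}} (weight crossing its boundary). Cached 1-D and 2-D cumulative
#' sums make both O(1) per query after an O(n^2) pass.
#'
#' @param M a \code{\link{contact_matrix}}.
#' @return object of class \code{"prefix_sums"}: list with \code{n},
#'   \code{row_sum} (per-bin volumes \eqn{V(b_i)}), \code{row_cum} (their
#'   cumulative sum, length n+1), \code{rect} ((n+1) x (n+1) 2-D cumulative
#'   sum of x) and \code{two_m} (total weight \eqn{2m = \sum_{ij} x_{ij}}).
#'   An all-zero matrix (\code{two_m == 0}) is rejected as degenerate:
#'   entropy is undefined without any interaction weight.
#' @export
prefix_sums <- function(M) {
  stopifnot(inherits(M, "contact_matrix"))
  x <- M$values
  n <- M$n
  two_m <- sum(x)
  if (two_m <= 0)
    stop("degenerate contact matrix: total weight 2m is zero", call. = FALSE)
  row_sum <- rowSums(x)
  rect <- matrix(0, n + 1L, n + 1L)
  rect[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum)
  # rect[i+1, j+1] = sum of x[1..i, 1..j]; note the double-apply transposes
  rect[-1L, -1L] <- t(rect[-1L, -1L, drop = FALSE])
  structure(list(n = n, row_sum = row_sum,
                 row_cum = c(0, cumsum(row_sum)),
                 rect = rect, two_m = two_m),
            class = "prefix_sums")
}

check_interval <- function(P, iv) {
  if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L] ||
      iv[1L] < 1L || iv[2L] > P$n)
    stop("invalid bin interval [", iv[1L], ", ", iv[2L], "] for n = ", P$n,
         call. = FALSE)
  as.integer(iv)
}

#' Volume of a bin interval
#'
#' \eqn{V(u) = \sum_{i \in u} \sum_j x_{ij}}; the full interval has volume
#' \eqn{2m}.
#'
#' @param P a \code{\link{prefix_sums}} object.
#' @param iv integer interval \code{c(start, end)}, 1-based inclusive.
#' @return non-negative scalar.
#' @export
volume <- function(P, iv) {
  iv <- check_interval(P, iv)
  P$row_cum[iv[2L] + 1L] - P$row_cum[iv[1L]]
}

rect_sum <- function(P, r1, r2, c1, c2) {
  P$rect[r2 + 1L, c2 + 1L] - P$rect[r1, c2 + 1L] -
    P$rect[r2 + 1L, c1] + P$rect[r1, c1]
}

#' Cut weight of a bin interval
#'
#' \eqn{g(u) = \sum_{i \in u, j \notin u} x_{ij}}: the interaction weight
#' leaving the interval. For a single bin \eqn{g = V} (the diagonal is zero).
#'
#' @inheritParams volume
#' @return non-negative scalar.
#' @export
cut_weight <- function(P, iv) {
  iv <- check_interval(P, iv)
  v <- P$row_cum[iv[2L] + 1L] - P$row_cum[iv[1L]]
  max(0, v - rect_sum(P, iv[1L], iv[2L], iv[1L], iv[2L]))
}

#' Structural entropy of a tree node
#'
#' The entropy of a node \eqn{u} with parent \eqn{p} is
#' \deqn{S(u) = -\frac{g(u)}{2m} \log_2 \frac{V(u)}{V(p)},}
#' the code length (in bits, weighted by boundary-crossing traffic) of the
#' step from the parent's interval to the node's. With the convention
#' \eqn{0 \cdot \log(\cdot) = 0}, terms with \eqn{g(u) = 0} or
#' \eqn{V(u) = 0} (e.g. unmappable all-zero bins) contribute 0, as does a
#' child equal to its parent. Always non-negative since
#' \eqn{V(u) \le V(p)}.
#'
#' @inheritParams volume
#' @param child,parent intervals \code{c(start, end)} with
#'   \code{child} contained in \code{parent}.
#' @return entropy in bits (non-negative scalar).
#' @export
node_entropy <- function(P, child, parent) {
  child <- check_interval(P, child)
  parent <- check_interval(P, parent)
  if (child[1L] < parent[1L] || child[2L] > parent[2L])
    stop("child interval not contained in parent interval", call. = FALSE)
  if (child[1L] == parent[1L] && child[2L] == parent[2L]) return(0)
  g <- cut_weight(P, child)
  v <- volume(P, child)
  vp <- volume(P, parent)
  if (g <= 0 || v <= 0 || vp <= 0) return(0)
  -(g / P$two_m) * log2(v / vp)
}

#' Bin-level structural entropy of a leaf interval
#'
#' Each bin \eqn{b_i} contributes
#' \eqn{-(g(b_i)/2m) \log_2(V(b_i)/V(e(b_i)))} where \eqn{e(b_i)} is the leaf
#' containing it and, with a zero diagonal, \eqn{g(b_i) = V(b_i)} is the
#' bin's row sum. Single-bin leaves and zero bins contribute 0.
#'
#' @inheritParams volume
#' @param leaf leaf interval \code{c(start, end)}.
#' @return entropy in bits.
#' @export
leaf_bin_entropy <- function(P, leaf) {
  leaf <- check_interval(P, leaf)
  vl <- volume(P, leaf)
  if (vl <= 0) return(0)
  rs <- P$row_sum[leaf[1L]:leaf[2L]]
  rs <- rs[rs > 0]
  if (length(rs) == 0L) return(0)
  sum(-(rs / P$two_m) * log2(rs / vl))
}

#' Structural entropy of a coding tree
#'
#' The total structural entropy is the sum of the node terms over all
#' non-root nodes plus the bin terms over all bins (grouped here by leaf):
#' \deqn{S_T(X) = \sum_{u \in T} S_T(X; u) + \sum_i S_T(X; b_i).}
#' The root contributes 0. This is the objective the detection modes
#' minimize: the coding tree of minimal structural entropy best separates
#' domain structure from random interaction noise.
#'
#' @inheritParams volume
#' @param tree a \code{\link{coding_tree}} over the same bin count.
#' @return entropy in bits.
#' @export
tree_entropy <- function(P, tree) {
  stopifnot(inherits(tree, "coding_tree"))
  if (tree$n != P$n)
    stop("tree and matrix bin counts differ (", tree$n, " vs ", P$n, ")",
         call. = FALSE)
  nd <- tree$nodes
  total <- 0
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent[i]
    if (!is.na(p))
      total <- total + node_entropy(P, c(nd$start[i], nd$end[i]),
                                    c(nd$start[p], nd$end[p]))
  }
  lv <- tree_leaves(tree)
  for (i in seq_len(nrow(lv)))
    total <- total + leaf_bin_entropy(P, c(lv$start[i], lv$end[i]))
  total
}

#' Contact density of a bin interval
#'
#' Intra-interval contact sum (each unordered pair counted once, i.e. the
#' upper triangle) divided by the interval length in bins. Used to
#' characterize how self-dense a detected domain is.
#'
#' @inheritParams volume
#' @return non-negative scalar (counts per bin).
#' @export
contact_density <- function(P, iv) {
  iv <- check_interval(P, iv)
  intra <- rect_sum(P, iv[1L], iv[2L], iv[1L], iv[2L]) / 2
  intra / (iv[2L] - iv[1L] + 1L)
}
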