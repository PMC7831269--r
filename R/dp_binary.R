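#' Optimal binary coding tree with k leaves
#'
#' Exact dynamic program over interval partitions: writing \eqn{S(l:r, k)}
#' for the minimal entropy of a binary subtree over bins \eqn{[l..r]} with
#' \eqn{k} leaves (its own node term excluded -- it is added by the caller,
#' and is zero at the root),
#' \deqn{S(l:r, k) = \min_{l \le i < r,\; 1 \le k_1 < k}
#'   \{ S(l:i, k_1) + S(i+1:r, k - k_1) + H_l + H_r \},}
#' where \eqn{H_l, H_r} are the node terms of the two children against the
#' parent \eqn{[l..r]}, with base case \eqn{S(l:r, 1)} equal to the leaf's
#' bin-level entropy. Since a binary tree of minimal entropy always exists
#' among coding trees with a given number of leaves, the result is the global
#' optimum over all coding trees with \code{k} leaves. Cost O(k^2 n^3); ties
#' are broken toward the smallest split index, then the smallest left leaf
#' count, so output is deterministic.
#'
#' @param P a \code{\link{prefix_sums}} object.
#' @param k number of leaves, \code{1 <= k <= n}.
#' @return list with \code{tree} (a \code{\link{coding_tree}}) and
#'   \code{entropy} (bits); \code{tree_entropy(P, tree) == entropy}.
#' @export
optimal_binary_tree <- function(P, k) {
  stopifnot(inherits(P, "prefix_sums"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > P$n)
    stop("'k' must be in [1, n]", call. = FALSE)
  res <- .dp_binary_cpp(P$row_cum, P$rect, P$two_m, k)
  list(tree = tree_from_cpp(res$trees[[k]], P$n), entropy = res$entropy[k])
}

#' Optimal entropy profile over the number of leaves
#'
#' Runs the binary DP once up to \code{k_max} and reports, for each
#' \eqn{k = 1, \ldots, k_{max}}, the optimal tree and its entropy. The
#' entropies are non-increasing in \eqn{k}: splitting any leaf of an optimal
#' tree never increases the total entropy.
#'
#' @inheritParams optimal_binary_tree
#' @param k_max largest leaf count to profile, \code{1 <= k_max <= n}.
#' @return list with \code{k} (integer vector), \code{entropy} (numeric,
#'   non-increasing) and \code{trees} (list of \code{\link{coding_tree}}s).
#' @export
entropy_vs_k <- function(P, k_max) {
  stopifnot(inherits(P, "prefix_sums"))
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 1L || k_max > P$n)
    stop("'k_max' must be in [1, n]", call. = FALSE)
  res <- .dp_binary_cpp(P$row_cum, P$rect, P$two_m, k_max)
  list(k = seq_len(k_max), entropy = res$entropy,
       trees = lapply(res$trees, tree_from_cpp, n = P$n))
}

# all ordered binary trees over [a..b] with exactly k leaves, as lists of
# node data.frames (parent relative to local root = row 1)
enumerate_binary <- function(a, b, k) {
  if (k == 1L)
    return(list(data.frame(parent = NA_integer_, start = a, end = b)))
  if (k > b - a + 1L) return(list())
  out <- list()
  for (i in a:(b - 1L)) {
    for (k1 in seq_len(k - 1L)) {
      if (k1 > i - a + 1L || k - k1 > b - i) next
      for (lt in enumerate_binary(a, i, k1)) {
        for (rt in enumerate_binary(i + 1L, b, k - k1)) {
          lt2 <- lt; rt2 <- rt
          lt2$parent <- lt2$parent + 1L
          lt2$parent[1L] <- 1L
          rt2$parent <- rt2$parent + 1L + nrow(lt2)
          rt2$parent[1L] <- 1L
          out[[length(out) + 1L]] <- rbind(
            data.frame(parent = NA_integer_, start = a, end = b), lt2, rt2)
        }
      }
    }
  }
  out
}

#' Brute-force optimal binary tree (independent test oracle)
#'
#' Exhaustively enumerates every ordered binary coding tree with exactly
#' \code{k} leaves and evaluates each with \code{\link{tree_entropy}},
#' independently of the dynamic-programming recurrence. Only feasible for
#' small matrices (refuses \code{n > 10}).
#'
#' @inheritParams optimal_binary_tree
#' @return list with \code{tree} and \code{entropy} as in
#'   \code{\link{optimal_binary_tree}}.
#' @export
brute_force_optimal <- function(P, k) {
  stopifnot(inherits(P, "prefix_sums"))
  if (P$n > 10L)
    stop("brute-force enumeration refused for n > 10", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > P$n)
    stop("'k' must be in [1, n]", call. = FALSE)
  best <- NULL
  best_e <- Inf
  for (nd in enumerate_binary(1L, P$n, k)) {
    tr <- coding_tree(nd, P$n)
    e <- tree_entropy(P, tr)
    if (e < best_e - 1e-12) {
      best_e <- e
      best <- tr
    }
  }
  list(tree = best, entropy = best_e)
}
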