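#' Structural entropy of the leaf-level partition
#'
#' The leaves of a coding tree induce a one-level coding of the matrix: each
#' leaf is taken as a direct domain of the whole genome. Its entropy is the
#' sum, over leaves \eqn{u}, of the node term
#' \eqn{-(g(u)/2m)\log_2(V(u)/2m)} plus the bin-level terms inside \eqn{u}.
#' As the number of leaves grows this quantity first drops -- leaves shrink
#' toward true domains, so the bin terms fall while boundary cuts stay small
#' -- and then rises once leaves start splitting real domains and their cuts
#' grow; its minimum marks a natural number of leaf domains.
#'
#' @param P a \code{\link{prefix_sums}} object.
#' @param tree a \code{\link{coding_tree}}.
#' @return entropy in bits. For a root-only tree this equals the bin-level
#'   entropy of the undivided matrix.
#' @export
leaf_node_entropy_sum <- function(P, tree) {
  stopifnot(inherits(tree, "coding_tree"))
  if (tree$n != P$n)
    stop("tree and matrix bin counts differ", call. = FALSE)
  lv <- tree_leaves(tree)
  root <- c(1L, P$n)
  total <- 0
  for (i in seq_len(nrow(lv))) {
    iv <- c(lv$start[i], lv$end[i])
    total <- total + node_entropy(P, iv, root) + leaf_bin_entropy(P, iv)
  }
  total
}

#' Select the number of leaf domains
#'
#' Profiles the optimal binary tree over \eqn{k = 2, \ldots, k_{max}} and
#' returns the \eqn{k} whose leaves minimize the leaf-level partition
#' entropy (\code{\link{leaf_node_entropy_sum}}), ties to the smallest
#' \eqn{k}. \eqn{k = 1} is excluded from the search: the criterion's
#' drop-then-rise shape presupposes at least two leaves, and a single
#' all-spanning domain is not a useful TAD call.
#'
#' The default \code{k_max} of \code{min(n, ceiling(n / 2) + 1)} reflects
#' that a domain of fewer than two bins is rarely meaningful, and bounds the
#' O(k^2 n^3) cost of the profile.
#'
#' @inheritParams leaf_node_entropy_sum
#' @param k_max largest leaf count to consider, \code{2 <= k_max <= n}.
#' @return list with \code{k} (the selected leaf count), \code{tree} (its
#'   optimal binary tree), \code{entropy} (its total entropy),
#'   \code{profile} (data frame with one row per candidate \code{k}:
#'   columns \code{k}, \code{total_entropy}, \code{leaf_entropy}) and
#'   \code{trees} (optimal trees for every \code{k} up to \code{k_max}).
#' @export
select_k <- function(P, k_max = NULL) {
  stopifnot(inherits(P, "prefix_sums"))
  if (is.null(k_max)) k_max <- min(P$n, ceiling(P$n / 2) + 1L)
  k_max <- as.integer(k_max)
  if (is.na(k_max) || k_max < 2L || k_max > P$n)
    stop("'k_max' must be in [2, n]", call. = FALSE)
  prof <- entropy_vs_k(P, k_max)
  ks <- 2L:k_max
  leaf_sum <- vapply(ks, function(k) leaf_node_entropy_sum(P, prof$trees[[k]]),
                     numeric(1))
  best <- ks[which.min(leaf_sum)]  # which.min takes the first minimum
  list(k = best,
       tree = prof$trees[[best]],
       entropy = prof$entropy[best],
       profile = data.frame(k = ks,
                            total_entropy = prof$entropy[ks],
                            leaf_entropy = leaf_sum),
       trees = prof$trees)
}
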