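#' Coding trees: ordered hierarchies of bin intervals
#'
#' A coding tree is an ordered hierarchy whose nodes code consecutive bin
#' intervals: the root codes all of \code{[1, n]}, the children of any node
#' partition their parent's interval in order, and the leaves therefore
#' partition the whole bin sequence. Every internal node has at least two
#' children (a single child would code the same interval as its parent and
#' carry zero structural entropy, i.e. be redundant). Each node is a TAD
#' candidate; the hierarchy encodes TADs, sub-TADs and meta-TADs.
#'
#' Internally a tree is a node table with columns \code{id}, \code{parent}
#' (\code{NA} for the root), \code{start}, \code{end} (1-based inclusive bin
#' coordinates).
#'
#' @param nodes data frame with columns \code{parent}, \code{start},
#'   \code{end}; row order is free, node ids are row numbers. Exactly one row
#'   must have \code{parent = NA} and span \code{[1, n]}.
#' @param n bin count the tree is defined over.
#' @return an object of class \code{"coding_tree"}: list with \code{nodes}
#'   (validated, with \code{id} column) and \code{n}.
#' @export
coding_tree <- function(nodes, n) {
  n <- as.integer(n)
  stopifnot(is.data.frame(nodes), n >= 1L)
  req <- c("parent", "start", "end")
  if (!all(req %in% names(nodes)))
    stop("'nodes' needs columns parent, start, end", call. = FALSE)
  nodes <- data.frame(id = seq_len(nrow(nodes)),
                      parent = as.integer(nodes$parent),
                      start = as.integer(nodes$start),
                      end = as.integer(nodes$end))
  root <- which(is.na(nodes$parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root (parent = NA)", call. = FALSE)
  if (nodes$start[root] != 1L || nodes$end[root] != n)
    stop("root must span [1, n]", call. = FALSE)
  if (any(nodes$start > nodes$end) || any(nodes$start < 1L) ||
      any(nodes$end > n))
    stop("node intervals must be non-empty and within [1, n]", call. = FALSE)
  for (id in nodes$id) {
    kids <- nodes[which(nodes$parent == id), , drop = FALSE]
    if (nrow(kids) == 0L) next
    if (nrow(kids) == 1L)
      stop("node ", id, " has a single child (redundant node)", call. = FALSE)
    kids <- kids[order(kids$start), , drop = FALSE]
    if (kids$start[1L] != nodes$start[id] ||
        kids$end[nrow(kids)] != nodes$end[id] ||
        (nrow(kids) > 1L &&
         any(kids$start[-1L] != kids$end[-nrow(kids)] + 1L)))
      stop("children of node ", id,
           " do not tile the parent interval consecutively", call. = FALSE)
  }
  structure(list(nodes = nodes, n = n), class = "coding_tree")
}

#' Build a flat coding tree from a leaf partition
#'
#' Convenience constructor for the height-1 tree whose root's children are
#' the given consecutive intervals.
#'
#' @param ends increasing vector of interval right ends; the last must be
#'   \code{n}. A single end equal to \code{n} gives the root-only tree.
#' @param n bin count.
#' @return a \code{\link{coding_tree}}.
#' @export
partition_tree <- function(ends, n) {
  ends <- as.integer(ends)
  stopifnot(length(ends) >= 1L, all(diff(ends) > 0L), ends[length(ends)] == n)
  if (length(ends) == 1L)
    return(coding_tree(data.frame(parent = NA, start = 1L, end = n), n))
  starts <- c(1L, ends[-length(ends)] + 1L)
  nodes <- data.frame(parent = c(NA, rep(1L, length(ends))),
                      start = c(1L, starts), end = c(n, ends))
  coding_tree(nodes, n)
}

tree_root_id <- function(tree) tree$nodes$id[is.na(tree$nodes$parent)]

# node tables from the C++ level mark the root with parent 0
tree_from_cpp <- function(nodes, n) {
  nodes$parent[nodes$parent == 0L] <- NA_integer_
  coding_tree(nodes, n)
}

tree_children <- function(tree, id) {
  kids <- tree$nodes[which(tree$nodes$parent == id), , drop = FALSE]
  kids[order(kids$start), , drop = FALSE]
}

#' Leaf intervals of a coding tree
#'
#' @param tree a \code{\link{coding_tree}}.
#' @return data frame of leaf rows (nodes without children), ordered by
#'   \code{start}; their intervals partition \code{[1, n]}.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "coding_tree"))
  has_kids <- tree$nodes$id %in% tree$nodes$parent
  lv <- tree$nodes[!has_kids, , drop = FALSE]
  lv[order(lv$start), , drop = FALSE]
}

#' Depth of each node (root = 0)
#' @param tree a \code{\link{coding_tree}}.
#' @return integer vector indexed by node id.
#' @export
tree_levels <- function(tree) {
  stopifnot(inherits(tree, "coding_tree"))
  lvl <- integer(nrow(tree$nodes))
  # repeated sweeps; tree depth bounds the number of passes
  for (pass in seq_len(nrow(tree$nodes))) {
    changed <- FALSE
    for (i in seq_len(nrow(tree$nodes))) {
      p <- tree$nodes$parent[i]
      if (!is.na(p) && lvl[i] != lvl[p] + 1L) {
        lvl[i] <- lvl[p] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lvl
}

#' @export
print.coding_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat("coding_tree: ", x$n, " bins, ", nrow(x$nodes), " nodes, ",
      nrow(lv), " leaves, height ", max(tree_levels(x)), "\n", sep = "")
  invisible(x)
}
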