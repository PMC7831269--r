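#' Partitions of the bin axis into domain intervals
#'
#' A partition is an ordered list of disjoint, non-empty bin intervals over a
#' common axis of \code{n} bins -- typically the leaf level of a coding tree
#' or the rows of a domain file. Intervals need not cover every bin
#' (inter-TAD gaps are allowed); the measure of concordance requires a full
#' tiling, which \code{\link{fill_partition_gaps}} provides.
#'
#' @param intervals two-column matrix or data frame of \code{start}, \code{end}
#'   (1-based inclusive), rows sorted or sortable by \code{start}.
#' @param n common bin count.
#' @return object of class \code{"tad_partition"}: list with \code{start},
#'   \code{end} (integer vectors) and \code{n}.
#' @export
tad_partition <- function(intervals, n) {
  n <- as.integer(n)
  intervals <- as.data.frame(intervals)
  if (ncol(intervals) < 2L)
    stop("'intervals' needs two columns (start, end)", call. = FALSE)
  start <- as.integer(intervals[[1L]])
  end <- as.integer(intervals[[2L]])
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) == 0L)
    stop("partition must contain at least one interval", call. = FALSE)
  if (any(start > end) || any(start < 1L) || any(end > n))
    stop("intervals must be non-empty and within [1, n]", call. = FALSE)
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stop("intervals must be pairwise disjoint", call. = FALSE)
  structure(list(start = start, end = end, n = n), class = "tad_partition")
}

#' Leaf (or all-node) intervals of a coding tree as a partition
#'
#' @param tree a \code{\link{coding_tree}}.
#' @param nodes \code{"leaves"} (default; the level at which domains cannot
#'   be subdivided further) or \code{"all"} for every non-root node as a
#'   multiset of intervals. \code{"all"} is only valid for the matching-based
#'   overlapping ratio / weighted similarity, not for the measure of
#'   concordance (the intervals overlap).
#' @return a \code{\link{tad_partition}}; with \code{nodes = "all"} its
#'   intervals may overlap (nested nodes), which the constructor's
#'   disjointness check would reject, so the object is assembled directly.
#' @export
partition_from_tree <- function(tree, nodes = c("leaves", "all")) {
  stopifnot(inherits(tree, "coding_tree"))
  nodes <- match.arg(nodes)
  if (nodes == "leaves") {
    lv <- tree_leaves(tree)
    return(tad_partition(lv[, c("start", "end")], tree$n))
  }
  nd <- tree$nodes[!is.na(tree$nodes$parent), , drop = FALSE]
  nd <- nd[order(nd$start, nd$end), , drop = FALSE]
  structure(list(start = nd$start, end = nd$end, n = tree$n),
            class = "tad_partition")
}

#' Overlap (shared bins) of two intervals
#' @param a,b integer intervals \code{c(start, end)}, 1-based inclusive.
#' @return non-negative integer bin count.
#' @export
interval_overlap <- function(a, b) {
  max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L)
}

check_common_axis <- function(X, Y) {
  stopifnot(inherits(X, "tad_partition"), inherits(Y, "tad_partition"))
  if (X$n != Y$n)
    stop("partitions are defined over different bin counts (", X$n, " vs ",
         Y$n, ")", call. = FALSE)
}

overlap_matrix <- function(X, Y) {
  outer(seq_along(X$start), seq_along(Y$start), function(i, j) {
    pmax(0L, pmin(X$end[i], Y$end[j]) - pmax(X$start[i], Y$start[j]) + 1L)
  })
}

# exact maximum-weight bipartite matching value via igraph (Hungarian path)
max_matching_weight <- function(w) {
  pos <- which(w > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(0)
  nx <- nrow(w); ny <- ncol(w)
  edges <- rbind(pos[, 1L], nx + pos[, 2L])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nx), rep(TRUE, ny)),
                                    as.vector(edges))
  igraph::E(g)$weight <- w[pos]
  igraph::max_bipartite_match(g)$matching_weight
}

#' Overlapping ratio between two partitions
#'
#' Builds the complete bipartite graph between the intervals of \code{X} and
#' \code{Y} with edge weights \eqn{w(x_i; y_j) = |x_i \cap y_j|}, finds a
#' maximum-weight matching \eqn{M}, and scores
#' \deqn{S(X, Y) = \frac{\sum_i w'(x_i; *) + \sum_j w'(*; y_j)}
#'   {\sum_i |x_i| + \sum_j |y_j|},}
#' i.e. twice the matching weight over the total interval mass. Symmetric,
#' in \eqn{[0, 1]}; 1 iff the partitions coincide, 0 iff no pair of
#' intervals intersects.
#'
#' @param X,Y \code{\link{tad_partition}}s over a common bin count.
#' @return scalar in \eqn{[0, 1]}.
#' @export
overlapping_ratio <- function(X, Y) {
  check_common_axis(X, Y)
  w <- overlap_matrix(X, Y)
  tot <- sum(X$end - X$start + 1L) + sum(Y$end - Y$start + 1L)
  2 * max_matching_weight(w) / tot
}

#' Weighted similarity of a partition against a reference
#'
#' \deqn{ws_X^Y = \frac{\sum_j |y_j| \cdot S_X^Y(j)}{\sum_j |y_j|}, \qquad
#'   S_X^Y(j) = \max_i \frac{|x_i \cap y_j|}{\sqrt{|x_i| \, |y_j|}}.}
#' Asymmetric: \code{X} is the reference (e.g. the true planted structure)
#' and \code{Y} the evaluated result.
#'
#' @param X reference \code{\link{tad_partition}}.
#' @param Y evaluated \code{\link{tad_partition}} on the same axis.
#' @return scalar in \eqn{[0, 1]}.
#' @export
weighted_similarity <- function(X, Y) {
  check_common_axis(X, Y)
  w <- overlap_matrix(X, Y)
  lx <- X$end - X$start + 1L
  ly <- Y$end - Y$start + 1L
  sj <- vapply(seq_along(ly), function(j)
    max(w[, j] / sqrt(lx * ly[j])), numeric(1))
  sum(ly * sj) / sum(ly)
}

#' Fill inter-domain gaps so a partition tiles the axis
#'
#' Maximal uncovered runs of bins become additional intervals, so that the
#' partition covers \code{[1, n]} completely -- the form required by the
#' measure of concordance, in which inter-TAD regions take part in the
#' assessment.
#'
#' @param X a \code{\link{tad_partition}}.
#' @return a tiling \code{\link{tad_partition}}.
#' @export
fill_partition_gaps <- function(X) {
  stopifnot(inherits(X, "tad_partition"))
  covered <- rep(FALSE, X$n)
  for (i in seq_along(X$start)) covered[X$start[i]:X$end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gs <- starts[!r$values]; ge <- ends[!r$values]
  tad_partition(data.frame(start = c(X$start, gs), end = c(X$end, ge)), X$n)
}

#' Measure of concordance between two tiling partitions
#'
#' \deqn{MoC(X, Y) = \frac{1}{\sqrt{N_X N_Y} - 1}
#'   \left( \sum_{i,j} \frac{|F_{ij}|^2}{|X_i| \, |Y_j|} - 1 \right)}
#' with \eqn{F_{ij}} the intersection of \eqn{X_i} and \eqn{Y_j}, and 1 by
#' convention when both partitions consist of a single interval. Symmetric,
#' in \eqn{[0, 1]}; requires both partitions to tile \eqn{[1, n]} (fill
#' inter-domain gaps first with \code{\link{fill_partition_gaps}}).
#'
#' @inheritParams overlapping_ratio
#' @return scalar in \eqn{[0, 1]}.
#' @export
moc <- function(X, Y) {
  check_common_axis(X, Y)
  for (Z in list(X, Y))
    if (sum(Z$end - Z$start + 1L) != Z$n)
      stop("partition does not tile [1, n]; fill gaps first", call. = FALSE)
  nx <- length(X$start)
  ny <- length(Y$start)
  if (nx == 1L && ny == 1L) return(1)
  w <- overlap_matrix(X, Y)
  lx <- X$end - X$start + 1L
  ly <- Y$end - Y$start + 1L
  (sum(w^2 / outer(lx, ly)) - 1) / (sqrt(nx * ny) - 1)
}
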