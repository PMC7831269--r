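#' Inherent interaction density of each tree node
#'
#' In a hierarchy, a node's raw mean interaction frequency mixes three
#' layers: the background its parent contributes, its own level, and the
#' denser cores of its children. To isolate the node's own contribution, a
#' top-down cascade first computes for every node \eqn{u} the mean
#' \eqn{\mu(u)} of \eqn{x_{ij}} over unordered bin pairs inside \eqn{u} but
#' not both inside the same child (for leaves: all intra pairs), then
#' deducts the inherent density already attributed to every proper ancestor:
#' \deqn{inherent(u) = \mu(u) - \sum_{a \; ancestor \; of \; u} inherent(a),}
#' with \eqn{inherent(root) = \mu(root)}. Single-bin nodes have no pairs and
#' get 0.
#'
#' @param P a \code{\link{prefix_sums}} object.
#' @param tree a \code{\link{coding_tree}}.
#' @return numeric vector indexed by node id.
#' @export
inherent_density <- function(P, tree) {
  stopifnot(inherits(tree, "coding_tree"))
  if (tree$n != P$n)
    stop("tree and matrix bin counts differ", call. = FALSE)
  nd <- tree$nodes
  intra <- function(s, e) rect_sum(P, s, e, s, e) / 2  # upper triangle
  npairs <- function(s, e) { len <- e - s + 1L; len * (len - 1L) / 2 }

  mu <- numeric(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    kids <- tree_children(tree, nd$id[i])
    s <- intra(nd$start[i], nd$end[i])
    cnt <- npairs(nd$start[i], nd$end[i])
    for (j in seq_len(nrow(kids))) {
      s <- s - intra(kids$start[j], kids$end[j])
      cnt <- cnt - npairs(kids$start[j], kids$end[j])
    }
    mu[i] <- if (cnt > 0) s / cnt else 0
  }

  lvl <- tree_levels(tree)
  inherent <- numeric(nrow(nd))
  for (i in order(lvl)) {
    if (nd$end[i] == nd$start[i]) { inherent[i] <- 0; next }
    anc_sum <- 0
    p <- nd$parent[i]
    while (!is.na(p)) {
      anc_sum <- anc_sum + inherent[p]
      p <- nd$parent[p]
    }
    inherent[i] <- mu[i] - anc_sum
  }
  inherent
}

#' Score nodes by repeated 2-means clustering
#'
#' Clusters the non-root nodes into two sets on standardized (size, inherent
#' density), repeating with random initialization. In Hi-C data contact
#' frequency decays with distance, so genuine TADs form the small-and-dense
#' cluster; per restart the selected cluster is the one whose members show a
#' negative rank relationship between size and density (Spearman), ties
#' resolved toward the higher mean density (then the smaller mean size). A
#' node's score is the fraction of restarts in which it fell in the selected
#' cluster. Deterministic for a fixed seed. If all feature vectors coincide
#' there is nothing to split and every node scores 1.
#'
#' @param features data frame with columns \code{id}, \code{size},
#'   \code{inherent_density}, one row per non-root node (see
#'   \code{\link{node_features}}).
#' @param restarts number of random initializations (default 1000).
#' @param seed integer RNG seed.
#' @return the input with a \code{selection_probability} column in
#'   \eqn{[0, 1]} filled in.
#' @export
cluster_and_score <- function(features, restarts = 1000L, seed = 1L) {
  stopifnot(is.data.frame(features),
            all(c("size", "inherent_density") %in% names(features)))
  restarts <- as.integer(restarts)
  if (is.na(restarts) || restarts < 1L)
    stop("'restarts' must be >= 1", call. = FALSE)
  m <- cbind(features$size, features$inherent_density)
  std <- apply(m, 2L, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  if (nrow(unique(std)) < 2L) {
    features$selection_probability <- 1
    return(features)
  }
  hits <- numeric(nrow(std))
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- std[sample(which(!duplicated(std)), 2L), , drop = FALSE]
      cl <- tryCatch(
        suppressWarnings(stats::kmeans(std, centers = centers,
                                       iter.max = 50L,
                                       algorithm = "Lloyd")$cluster),
        error = function(e) {
          # fall back to nearest-initial-center assignment
          d1 <- colSums((t(std) - centers[1L, ])^2)
          d2 <- colSums((t(std) - centers[2L, ])^2)
          ifelse(d1 <= d2, 1L, 2L)
        })
      sel <- select_dense_cluster(features$size, features$inherent_density,
                                  cl)
      hits[cl == sel] <- hits[cl == sel] + 1
    }
  })
  features$selection_probability <- hits / restarts
  features
}

# pick which of the two clusters holds TAD-like nodes: negative size-density
# rank correlation; ties toward higher mean density, then smaller mean size
select_dense_cluster <- function(size, dens, cl) {
  rho <- vapply(1:2, function(g) {
    i <- cl == g
    if (sum(i) < 2L) return(NA_real_)
    suppressWarnings(stats::cor(size[i], dens[i], method = "spearman"))
  }, numeric(1))
  neg <- !is.na(rho) & rho < 0
  if (sum(neg) == 1L) return(which(neg))
  mean_dens <- vapply(1:2, function(g) mean(dens[cl == g]), numeric(1))
  if (mean_dens[1L] != mean_dens[2L]) return(which.max(mean_dens))
  mean_size <- vapply(1:2, function(g) mean(size[cl == g]), numeric(1))
  which.min(mean_size)
}

#' Node feature table for filtering
#'
#' One row per non-root node with its size (bin count), structural entropy
#' term, parent's entropy term, and inherent density.
#'
#' @inheritParams inherent_density
#' @return data frame with columns \code{id}, \code{size}, \code{entropy},
#'   \code{parent_entropy}, \code{inherent_density}.
#' @export
node_features <- function(P, tree) {
  nd <- tree$nodes
  inh <- inherent_density(P, tree)
  ent <- vapply(seq_len(nrow(nd)), function(i) {
    p <- nd$parent[i]
    if (is.na(p)) return(0)
    node_entropy(P, c(nd$start[i], nd$end[i]), c(nd$start[p], nd$end[p]))
  }, numeric(1))
  keep <- !is.na(nd$parent)
  data.frame(id = nd$id[keep],
             size = nd$end[keep] - nd$start[keep] + 1L,
             entropy = ent[keep],
             parent_entropy = ent[nd$parent[keep]],
             inherent_density = inh[keep])
}

#' Prune non-TAD nodes from a coding tree
#'
#' A node is discarded only if all three hold: its selection probability is
#' below \code{prob_threshold}; its structural entropy term is lower than
#' its parent's; and it splits its parent nearly in half
#' (\eqn{| size - size(parent)/2 | \le} \code{split_tolerance}
#' \eqn{\cdot size(parent)}) -- the signature of an arbitrary bisection
#' rather than a real domain. All other nodes are kept. Filtering never
#' alters intervals or entropies; it only flags records, and the root is
#' never emitted as a TAD.
#'
#' @inheritParams inherent_density
#' @param features output of \code{\link{cluster_and_score}} (must cover all
#'   non-root nodes and contain \code{selection_probability}).
#' @param prob_threshold keep any node scoring at least this (default 0.5).
#' @param split_tolerance relative tolerance for "close to equally split"
#'   (default 0.1).
#' @return data frame of domain records (see \code{\link{domain_records}})
#'   with the \code{kept} flag set.
#' @export
prune_domains <- function(P, tree, features, prob_threshold = 0.5,
                          split_tolerance = 0.1) {
  if (prob_threshold < 0 || prob_threshold > 1)
    stop("'prob_threshold' must be in [0, 1]", call. = FALSE)
  if (!"selection_probability" %in% names(features))
    stop("run cluster_and_score() first", call. = FALSE)
  rec <- domain_records(P, tree)
  nd <- tree$nodes
  psize <- nd$end[features$id] - nd$start[features$id] + 1L
  par <- nd$parent[features$id]
  parent_size <- nd$end[par] - nd$start[par] + 1L
  discard <- features$selection_probability < prob_threshold &
    features$entropy < features$parent_entropy &
    abs(psize - parent_size / 2) <= split_tolerance * parent_size
  rec$kept <- !discard[match(rec$id, features$id)]
  rec
}
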