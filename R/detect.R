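#' Detect a TAD hierarchy from a contact matrix
#'
#' The main entry point. Two modes:
#' \describe{
#'   \item{\code{"auto"}}{parameter-free: profiles optimal binary coding
#'     trees over the leaf count and selects the one minimizing the
#'     leaf-node entropy sum (\code{\link{select_k}}). Optionally prunes
#'     non-TAD nodes afterwards (\code{filter = TRUE}).}
#'   \item{\code{"height"}}{finds the exact optimal multi-nary coding tree
#'     of height at most \code{h} (\code{\link{optimal_tree_height}});
#'     \code{h = 2} gives a two-level hierarchy.}
#' }
#'
#' @param M a \code{\link{contact_matrix}}.
#' @param mode \code{"auto"} (default) or \code{"height"}.
#' @param h height bound for \code{mode = "height"} (default 2).
#' @param k_max cap on the number of leaf domains (default
#'   \code{min(n, ceiling(n/2) + 1)}).
#' @param filter apply node filtering (auto mode; default \code{FALSE}).
#' @param restarts,filter_seed,prob_threshold,split_tolerance filter
#'   settings, see \code{\link{cluster_and_score}} and
#'   \code{\link{prune_domains}}.
#' @param verbose print a short run summary.
#' @return object of class \code{"tad_detection"}: list with \code{tree},
#'   \code{entropy} (total structural entropy, bits), \code{k} (leaf
#'   count), \code{records} (domain records with \code{kept} flags),
#'   \code{mode}, and the \code{matrix} metadata.
#' @export
detect_tads <- function(M, mode = c("auto", "height"), h = 2L, k_max = NULL,
                        filter = FALSE, restarts = 1000L, filter_seed = 1L,
                        prob_threshold = 0.5, split_tolerance = 0.1,
                        verbose = FALSE) {
  stopifnot(inherits(M, "contact_matrix"))
  mode <- match.arg(mode)
  P <- prefix_sums(M)
  if (is.null(k_max)) k_max <- min(P$n, ceiling(P$n / 2) + 1L)

  if (mode == "auto") {
    fit <- select_k(P, k_max = max(2L, k_max))
    tree <- fit$tree
    entropy <- fit$entropy
    k <- fit$k
  } else {
    fit <- optimal_tree_height(P, h = h, k_max = k_max)
    tree <- fit$tree
    entropy <- fit$entropy
    k <- fit$k
  }

  if (filter) {
    feats <- cluster_and_score(node_features(P, tree), restarts = restarts,
                               seed = filter_seed)
    records <- prune_domains(P, tree, feats, prob_threshold = prob_threshold,
                             split_tolerance = split_tolerance)
  } else {
    records <- domain_records(P, tree)
  }

  if (verbose)
    message("n = ", P$n, ", 2m = ", format(P$two_m), ", mode = ", mode,
            ", k = ", k, ", entropy = ", format(entropy), " bits, ",
            sum(records$kept), "/", nrow(records), " nodes kept")

  structure(list(tree = tree, entropy = entropy, k = k, records = records,
                 mode = mode, resolution = M$resolution, chrom = M$chrom,
                 start_bp = M$start_bp, n = P$n),
            class = "tad_detection")
}

#' @export
print.tad_detection <- function(x, ...) {
  cat("tad_detection (mode ", x$mode, "): ", x$n, " bins, k = ", x$k,
      ", entropy = ", format(x$entropy), " bits, ",
      sum(x$records$kept), "/", nrow(x$records), " domains kept\n", sep = "")
  invisible(x)
}

#' Compare two domain call sets
#'
#' Computes the overlapping ratio, both directions of the weighted
#' similarity, and the measure of concordance (on the gap-filled leaf
#' level) between two domain record sets over a common bin count.
#'
#' @param a,b domain record data frames (e.g. from
#'   \code{\link{read_domains}} or \code{\link{detect_tads}}'s
#'   \code{records}).
#' @param n common bin count.
#' @param nodes compare \code{"leaves"} (default) or \code{"all"} intervals
#'   for the matching-based metrics.
#' @return one-row data frame with columns \code{or}, \code{ws_ab},
#'   \code{ws_ba}, \code{moc}.
#' @export
compare_domains <- function(a, b, n, nodes = c("leaves", "all")) {
  nodes <- match.arg(nodes)
  part <- function(rec) domains_to_partition(rec, n)
  all_part <- function(rec) {
    if ("kept" %in% names(rec))
      rec <- rec[as.logical(rec$kept), , drop = FALSE]
    structure(list(start = as.integer(rec$start_bin),
                   end = as.integer(rec$end_bin), n = as.integer(n)),
              class = "tad_partition")
  }
  pa <- if (nodes == "leaves") part(a) else all_part(a)
  pb <- if (nodes == "leaves") part(b) else all_part(b)
  la <- part(a)
  lb <- part(b)
  data.frame(or = overlapping_ratio(pa, pb),
             ws_ab = weighted_similarity(pa, pb),
             ws_ba = weighted_similarity(pb, pa),
             moc = moc(fill_partition_gaps(la), fill_partition_gaps(lb)))
}
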