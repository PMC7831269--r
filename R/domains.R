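#' Domain records from a coding tree
#'
#' Flattens the non-root nodes of a coding tree into one record per domain
#' candidate: hierarchy level (children of the root are level 1), bin
#' interval, the node's structural entropy term (bits) and its contact
#' density (intra-domain contacts per bin). Records are ordered by level,
#' then start bin.
#'
#' @param P a \code{\link{prefix_sums}} object.
#' @param tree a \code{\link{coding_tree}}.
#' @return data frame with columns \code{id}, \code{level}, \code{start_bin},
#'   \code{end_bin}, \code{entropy}, \code{density}, \code{kept} (all
#'   \code{TRUE} before filtering).
#' @export
domain_records <- function(P, tree) {
  stopifnot(inherits(tree, "coding_tree"))
  nd <- tree$nodes
  lvl <- tree_levels(tree)
  keep <- !is.na(nd$parent)
  ent <- vapply(which(keep), function(i) {
    p <- nd$parent[i]
    node_entropy(P, c(nd$start[i], nd$end[i]), c(nd$start[p], nd$end[p]))
  }, numeric(1))
  dens <- vapply(which(keep), function(i)
    contact_density(P, c(nd$start[i], nd$end[i])), numeric(1))
  rec <- data.frame(id = nd$id[keep], level = lvl[keep],
                    start_bin = nd$start[keep], end_bin = nd$end[keep],
                    entropy = ent, density = dens, kept = TRUE)
  rec[order(rec$level, rec$start_bin), , drop = FALSE]
}

#' Write domain records as a TSV file
#'
#' Tab-separated with a header. Bin coordinates are 1-based inclusive; when
#' a resolution is supplied, BED-like genomic coordinates are added
#' (\code{start_bp = (start_bin - 1) * resolution + offset},
#' \code{end_bp = end_bin * resolution + offset}). Rows are ordered by
#' level, then start bin, so parents always precede their children.
#'
#' @param records data frame from \code{\link{domain_records}} or
#'   \code{\link{prune_domains}}.
#' @param path output path.
#' @param resolution optional bin size in bp.
#' @param chrom optional chromosome label (adds a \code{chrom} column).
#' @param start_bp genomic offset of bin 1 in bp (default 0).
#' @return the path, invisibly.
#' @export
write_domains <- function(records, path, resolution = NULL, chrom = NULL,
                          start_bp = 0L) {
  stopifnot(is.data.frame(records))
  out <- records[order(records$level, records$start_bin), , drop = FALSE]
  out$id <- NULL
  if (!is.null(resolution)) {
    out$start_bp <- (out$start_bin - 1L) * resolution + start_bp
    out$end_bp <- out$end_bin * resolution + start_bp
    ord <- c("level", "start_bin", "end_bin", "start_bp", "end_bp",
             "entropy", "density", "kept")
    out <- out[, ord]
  }
  if (!is.null(chrom)) out <- cbind(chrom = chrom, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a domain TSV back into a record data frame
#'
#' @param path path written by \code{\link{write_domains}}.
#' @return data frame with at least \code{level}, \code{start_bin},
#'   \code{end_bin} and, if present, \code{kept}.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Leaf-level partition from domain records
#'
#' Extracts the intervals that contain no other record's interval (the
#' domains that cannot be subdivided further), optionally restricted to
#' \code{kept} records.
#'
#' @param records a domain record data frame.
#' @param n bin count of the underlying matrix.
#' @param kept_only drop records flagged as filtered out (default
#'   \code{TRUE} when a \code{kept} column is present).
#' @return a \code{\link{tad_partition}}.
#' @export
domains_to_partition <- function(records, n, kept_only = TRUE) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (kept_only && "kept" %in% names(records))
    records <- records[as.logical(records$kept), , drop = FALSE]
  s <- records$start_bin
  e <- records$end_bin
  is_leaf <- vapply(seq_along(s), function(i) {
    inside <- s >= s[i] & e <= e[i] & !(s == s[i] & e == e[i])
    !any(inside)
  }, logical(1))
  tad_partition(data.frame(start = s[is_leaf], end = e[is_leaf]), n)
}
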