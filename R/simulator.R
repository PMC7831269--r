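#' Simulate a planted-block binary contact matrix
#'
#' Generates the adjacency matrix \eqn{A = \{a_{ij}\}} of a graph containing
#' consecutive, non-overlapping clusters: \eqn{a_{ij} = 1} with probability
#' \code{p_in} when bins \eqn{i, j} lie in the same cluster and with
#' probability \code{p_in * noise_ratio} otherwise (the noise ratio
#' expresses inter-cluster interaction as a fraction of intra-cluster
#' interaction). The matrix is symmetric with a zero diagonal. Cluster sizes
#' are drawn from a Gaussian with the given mean and standard deviation,
#' rounded, clipped at 2 bins; the last cluster absorbs the rounding drift
#' so the total equals the rounded sum of the raw draws (\code{size_sd = 0}
#' gives exactly equal sizes). Deterministic for a fixed seed.
#'
#' This emulates a flat planted-partition benchmark; it does not model the
#' distance decay of real Hi-C counts.
#'
#' @param n_clusters number of planted clusters.
#' @param mean_size mean cluster size in bins (\code{>= 2}).
#' @param size_sd standard deviation of the size distribution (bins).
#' @param p_in intra-cluster edge probability in \eqn{(0, 1]} (default 0.5).
#' @param noise_ratio inter/intra probability ratio in \eqn{[0, 1]}.
#' @param seed integer RNG seed.
#' @return list with \code{matrix} (a \code{\link{contact_matrix}}) and
#'   \code{truth}: list with \code{cluster_sizes}, \code{boundaries} (ends
#'   of each cluster), \code{partition} (a \code{\link{tad_partition}}),
#'   \code{p_in}, \code{noise_ratio}, \code{size_sd}, \code{seed}.
#' @export
simulate_block_matrix <- function(n_clusters, mean_size, size_sd = 0,
                                  p_in = 0.5, noise_ratio = 0, seed = 1L) {
  stopifnot(n_clusters >= 1L, mean_size >= 2)
  if (p_in <= 0 || p_in > 1)
    stop("'p_in' must be in (0, 1]", call. = FALSE)
  if (noise_ratio < 0 || noise_ratio > 1)
    stop("'noise_ratio' must be in [0, 1]", call. = FALSE)
  if (size_sd < 0) stop("'size_sd' must be >= 0", call. = FALSE)

  sim <- withr::with_seed(as.integer(seed), {
    raw <- stats::rnorm(n_clusters, mean_size, size_sd)
    sizes <- pmax(2L, as.integer(round(raw)))
    drift <- as.integer(round(sum(raw))) - sum(sizes)
    sizes[n_clusters] <- max(2L, sizes[n_clusters] + drift)
    n <- sum(sizes)
    ends <- cumsum(sizes)
    starts <- c(1L, ends[-n_clusters] + 1L)
    member <- rep(seq_len(n_clusters), sizes)
    p_out <- p_in * noise_ratio
    a <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      p <- ifelse(member[j] == member[i], p_in, p_out)
      a[i, j] <- as.numeric(stats::runif(length(j)) < p)
    }
    a <- a + t(a)
    list(a = a, sizes = sizes, ends = ends, starts = starts, n = n)
  })
  truth <- list(cluster_sizes = sim$sizes, boundaries = sim$ends,
                partition = tad_partition(
                  data.frame(start = sim$starts, end = sim$ends), sim$n),
                p_in = p_in, noise_ratio = noise_ratio, size_sd = size_sd,
                seed = as.integer(seed))
  list(matrix = contact_matrix(sim$a), truth = truth)
}

#' Noise-robustness recovery experiment
#'
#' For each noise ratio and replicate: simulate a planted-block matrix, run
#' the parameter-free detection mode (binary DP plus automatic leaf-count
#' selection), flatten the result to its leaf partition, and score it
#' against the planted partition with the overlapping ratio and the weighted
#' similarity (planted structure as the reference). The detected tree's
#' total structural entropy is recorded as well. Replicate \code{r} at the
#' \code{i}-th noise ratio uses seed \code{seed + (i - 1) * reps + (r - 1)},
#' so the whole table is reproducible from one seed.
#'
#' @inheritParams simulate_block_matrix
#' @param noise_ratios numeric vector of noise ratios to test.
#' @param reps replicates per noise ratio.
#' @param k_max optional cap on the leaf-count search (default as in
#'   \code{\link{select_k}}).
#' @return list with \code{results}: data frame with one row per
#'   (noise_ratio, replicate) and columns \code{noise_ratio}, \code{rep},
#'   \code{k}, \code{overlapping_ratio}, \code{weighted_similarity},
#'   \code{tree_entropy}; and \code{summary}: per-noise-ratio medians.
#' @export
recovery_experiment <- function(n_clusters, mean_size, size_sd = 0,
                                p_in = 0.5, noise_ratios = seq(0.05, 0.5, 0.05),
                                reps = 20L, seed = 1L, k_max = NULL) {
  rows <- vector("list", length(noise_ratios) * reps)
  idx <- 0L
  for (i in seq_along(noise_ratios)) {
    for (r in seq_len(reps)) {
      s <- as.integer(seed) + (i - 1L) * reps + (r - 1L)
      sim <- simulate_block_matrix(n_clusters, mean_size, size_sd, p_in,
                                   noise_ratios[i], seed = s)
      P <- prefix_sums(sim$matrix)
      fit <- select_k(P, k_max = k_max)
      found <- partition_from_tree(fit$tree)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        noise_ratio = noise_ratios[i], rep = r, k = fit$k,
        overlapping_ratio = overlapping_ratio(sim$truth$partition, found),
        weighted_similarity = weighted_similarity(sim$truth$partition, found),
        tree_entropy = fit$entropy)
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$noise_ratio),
    function(d) data.frame(
      noise_ratio = d$noise_ratio[1L],
      median_or = stats::median(d$overlapping_ratio),
      median_ws = stats::median(d$weighted_similarity),
      median_entropy = stats::median(d$tree_entropy))))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
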