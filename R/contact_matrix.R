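#' Construct and validate a Hi-C contact matrix
#'
#' A contact matrix holds the interaction frequencies \code{x[i, j]} between
#' \code{n} fixed-size genomic bins at a stated resolution. The matrix must be
#' symmetric, non-negative and finite; the diagonal is zero by construction
#' (self-contacts carry no information about domain structure), so nonzero
#' diagonal entries are zeroed with a warning.
#'
#' @param values numeric \code{n x n} matrix of interaction frequencies
#'   (raw or normalized counts).
#' @param resolution optional bin size in bp, used only to annotate output
#'   coordinates.
#' @param chrom optional chromosome label.
#' @param start_bp optional genomic offset of bin 1 (bp), default 0.
#' @param tol symmetry tolerance relative to the largest entry; asymmetry
#'   beyond it is an error rather than silently averaged, since an asymmetric
#'   dump usually signals a corrupted file.
#'
#' @return an object of class \code{"contact_matrix"}: a list with elements
#'   \code{values}, \code{n}, \code{resolution}, \code{chrom}, \code{start_bp}.
#' @export
contact_matrix <- function(values, resolution = NULL, chrom = NULL,
                           start_bp = 0L, tol = 1e-6) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop("contact matrix must be square, got ", nrow(values), " x ",
         ncol(values), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("contact matrix contains non-finite values", call. = FALSE)
  if (any(values < 0))
    stop("contact matrix contains negative values", call. = FALSE)
  scale <- max(1, max(values))
  asym <- max(abs(values - t(values)))
  if (asym > tol * scale)
    stop("contact matrix is asymmetric beyond tolerance (max |x_ij - x_ji| = ",
         format(asym), ")", call. = FALSE)
  # symmetrize residual float noise
  values <- (values + t(values)) / 2
  if (any(diag(values) != 0)) {
    warning("nonzero diagonal entries set to zero", call. = FALSE)
    diag(values) <- 0
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, n = nrow(values), resolution = resolution,
         chrom = chrom, start_bp = as.integer(start_bp)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix: ", x$n, " bins",
      if (!is.null(x$resolution)) paste0(" @ ", x$resolution, " bp"),
      if (!is.null(x$chrom)) paste0(" (", x$chrom, ")"),
      ", total weight 2m = ", format(sum(x$values)), "\n", sep = "")
  invisible(x)
}

#' Read a dense whitespace-delimited contact matrix
#'
#' Reads an \code{n x n} matrix from plain text, one row per line, no header.
#' All rows must have the same number of numeric tokens and the matrix must be
#' square and symmetric (within tolerance).
#'
#' @param path path to the text file.
#' @inheritParams contact_matrix
#' @return a \code{\link{contact_matrix}}.
#' @export
read_dense_matrix <- function(path, resolution = NULL, chrom = NULL,
                              start_bp = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path, call. = FALSE)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) stop("non-numeric entry in matrix file", call. = FALSE)
    v
  })
  len <- lengths(rows)
  if (length(unique(len)) != 1L)
    stop("ragged rows in matrix file (row lengths ",
         paste(unique(len), collapse = ", "), ")", call. = FALSE)
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m))
    stop("matrix file is not square: ", nrow(m), " rows x ", ncol(m),
         " columns", call. = FALSE)
  contact_matrix(m, resolution = resolution, chrom = chrom,
                 start_bp = start_bp)
}

#' Read a sparse triplet contact file
#'
#' Reads lines of the form \code{"i j value"} into a dense symmetric contact
#' matrix of known size. Missing entries are zero. If both \code{(i, j)} and
#' \code{(j, i)} occur they must agree within tolerance.
#'
#' @param path path to the 3-column text file.
#' @param n bin count of the target matrix.
#' @param one_based logical; are indices in the file 1-based (the common
#'   straw/dump convention, default) or 0-based?
#' @param tol tolerance for conflicting mirror/duplicate values.
#' @inheritParams contact_matrix
#' @return a \code{\link{contact_matrix}}.
#' @export
read_sparse_triplets <- function(path, n, one_based = TRUE, tol = 1e-6,
                                 resolution = NULL, chrom = NULL,
                                 start_bp = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("integer", "integer", "numeric"))
  if (ncol(tab) != 3L)
    stop("sparse triplet file must have exactly 3 columns", call. = FALSE)
  i <- tab[[1L]]; j <- tab[[2L]]; v <- tab[[3L]]
  if (!one_based) { i <- i + 1L; j <- j + 1L }
  if (any(i < 1L | i > n | j < 1L | j > n))
    stop("triplet index out of range [", if (one_based) "1" else "0", ", n]",
         call. = FALSE)
  if (any(!is.finite(v)) || any(v < 0))
    stop("triplet values must be finite and non-negative", call. = FALSE)
  m <- matrix(0, n, n)
  scale <- max(1, max(v, 0))
  for (r in seq_along(i)) {
    a <- i[r]; b <- j[r]
    for (idx in unique(list(c(a, b), c(b, a)))) {
      prev <- m[idx[1L], idx[2L]]
      if (prev != 0 && abs(prev - v[r]) > tol * scale)
        stop("conflicting values for entry (", a, ", ", b, "): ",
             format(prev), " vs ", format(v[r]), call. = FALSE)
      m[idx[1L], idx[2L]] <- v[r]
    }
  }
  diag(m) <- 0
  contact_matrix(m, resolution = resolution, chrom = chrom,
                 start_bp = start_bp)
}

#' Write a dense contact matrix as whitespace-delimited text
#'
#' Inverse of \code{\link{read_dense_matrix}} (round-trips within float
#' formatting precision).
#'
#' @param M a \code{\link{contact_matrix}}.
#' @param path output path.
#' @export
write_dense_matrix <- function(M, path) {
  stopifnot(inherits(M, "contact_matrix"))
  utils::write.table(M$values, path, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
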