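# BinnedContactMap: normalized contact values between fixed-size genomic
# bins of one chromosome, stored as a sparse upper-triangular matrix.

#' Build a binned contact map
#'
#' Container for normalized Hi-C contact values of one chromosome at a
#' fixed bin size (default 5 kb). Values are stored as a sparse
#' upper-triangular matrix; bin indices are 0-based externally (bin `i`
#' covers `[i*bin, (i+1)*bin)` bp, half-open).
#'
#' @param values Either a `data.frame` with columns `bin_i`, `bin_j`
#'   (0-based) and `value`, or a square (dense or `Matrix`) matrix. A
#'   symmetric matrix is reduced to its upper triangle; an asymmetric one
#'   with entries in both triangles is rejected.
#' @param chrom Chromosome identifier.
#' @param bin_size_kb Bin size in kb.
#' @param n_bins Number of bins; inferred from matrix dimensions or from
#'   the largest index when omitted.
#' @return A list of class `binned_contact_map` with elements `chrom`,
#'   `bin_size_kb`, `n_bins` and `mat` (sparse upper-triangular
#'   `dgCMatrix`).
#' @examples
#' contact_map(data.frame(bin_i = 0, bin_j = 1, value = 2.5),
#'             chrom = "chr2L", n_bins = 10)
#' @export
contact_map <- function(values, chrom = "chr", bin_size_kb = 5,
                        n_bins = NULL) {
  stopifnot(is.numeric(bin_size_kb), bin_size_kb > 0)
  if (is.data.frame(values)) {
    stopifnot(all(c("bin_i", "bin_j", "value") %in% names(values)))
    i <- values$bin_i
    j <- values$bin_j
    x <- values$value
    if (any(i < 0) || any(j < 0) || any(i != round(i)) || any(j != round(j))) {
      stop("bin indices must be non-negative integers")
    }
    if (is.null(n_bins)) n_bins <- max(i, j, 0) + 1L
    if (any(i >= n_bins) || any(j >= n_bins)) {
      stop("bin indices must lie in [0, n_bins)")
    }
    # fold into the upper triangle
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    mat <- Matrix::sparseMatrix(
      i = lo + 1L, j = hi + 1L, x = x, dims = c(n_bins, n_bins),
      repr = "C"
    )
  } else {
    mat <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix")
    if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
    if (is.null(n_bins)) n_bins <- nrow(mat)
    stopifnot(n_bins == nrow(mat))
    lower <- Matrix::tril(mat, k = -1)
    if (length(lower@x) && any(lower@x != 0)) {
      if (!Matrix::isSymmetric(mat, tol = 1e-8)) {
        stop("matrix has inconsistent lower-triangle entries; supply a ",
             "symmetric or upper-triangular matrix")
      }
      mat <- Matrix::triu(mat)
    }
  }
  mat <- Matrix::drop0(mat)
  if (length(mat@x)) {
    if (any(!is.finite(mat@x))) stop("contact values must be finite")
    if (any(mat@x < 0)) stop("contact values must be non-negative")
  }
  structure(
    list(chrom = as.character(chrom), bin_size_kb = bin_size_kb,
         n_bins = as.integer(n_bins), mat = mat),
    class = "binned_contact_map"
  )
}

#' @export
print.binned_contact_map <- function(x, ...) {
  cat(sprintf(
    "<binned_contact_map> %s: %d bins of %g kb, %d stored contacts\n",
    x$chrom, x$n_bins, x$bin_size_kb, length(x$mat@x)
  ))
  invisible(x)
}

#' Look up contact values by bin pair
#'
#' @param map A [contact_map()].
#' @param bin_i,bin_j 0-based bin index vectors (recycled to equal
#'   length); order is irrelevant (the map is symmetric).
#' @return Numeric vector of contact values (0 where absent).
#' @export
map_value <- function(map, bin_i, bin_j) {
  stopifnot(inherits(map, "binned_contact_map"))
  n <- max(length(bin_i), length(bin_j))
  bin_i <- rep_len(bin_i, n)
  bin_j <- rep_len(bin_j, n)
  lo <- pmin(bin_i, bin_j) + 1L
  hi <- pmax(bin_i, bin_j) + 1L
  stopifnot(all(lo >= 1), all(hi <= map$n_bins))
  map$mat[cbind(lo, hi)]
}
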