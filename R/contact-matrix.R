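#' Construct a per-chromosome contact matrix
#'
#' A `ContactMatrix` holds one chromosome's symmetric, non-negative binned
#' Hi-C contact map together with its bin metadata. Coordinates are 0-based,
#' half-open, with uniformly spaced bins of width `bin_size`.
#'
#' @param counts Square numeric matrix of non-negative contact counts.
#'   Must be symmetric (exactly for raw integer counts, to within `1e-9`
#'   relative tolerance for balanced values).
#' @param chrom Chromosome identifier (e.g. `"chr1"`).
#' @param bin_size Bin width in base pairs. Default 10000 (10 kb).
#' @param bin_starts Genomic start coordinate of each bin. Defaults to
#'   `0, bin_size, 2*bin_size, ...`. Must be ascending with uniform spacing
#'   equal to `bin_size`.
#' @param balanced Logical; has ICE balancing been applied?
#' @param mask Logical vector flagging bins excluded from analysis (e.g.
#'   low-coverage bins masked by [ice_normalize()]). Masked bins must carry
#'   all-zero rows/columns.
#'
#' @return An object of class `ContactMatrix`: a list with elements
#'   `counts`, `chrom`, `bin_size`, `bin_starts`, `balanced`, `mask`.
#' @examples
#' m <- contact_matrix(matrix(c(0, 5, 5, 0), 2), "chr1")
#' n_bins(m)
#' @export
contact_matrix <- function(counts, chrom, bin_size = 10000L,
                           bin_starts = NULL, balanced = FALSE,
                           mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("'counts' must be a square matrix", call. = FALSE)
  }
  n <- nrow(counts)
  if (is.null(bin_starts)) {
    bin_starts <- as.numeric(seq_len(n) - 1L) * bin_size
  }
  if (is.null(mask)) mask <- rep(FALSE, n)
  obj <- structure(
    list(counts = unname(counts), chrom = as.character(chrom),
         bin_size = as.integer(bin_size), bin_starts = as.numeric(bin_starts),
         balanced = isTRUE(balanced), mask = as.logical(mask)),
    class = "ContactMatrix")
  validate_contact_matrix(obj)
  obj
}

#' @rdname contact_matrix
#' @param x Object to test or query.
#' @export
is_contact_matrix <- function(x) inherits(x, "ContactMatrix")

#' @rdname contact_matrix
#' @export
n_bins <- function(x) {
  stopifnot(is_contact_matrix(x))
  nrow(x$counts)
}

validate_contact_matrix <- function(x) {
  counts <- x$counts
  n <- nrow(counts)
  if (length(x$bin_starts) != n) {
    stop("length(bin_starts) must equal the matrix dimension", call. = FALSE)
  }
  if (length(x$mask) != n) {
    stop("length(mask) must equal the matrix dimension", call. = FALSE)
  }
  if (any(counts < 0)) stop("contact counts must be non-negative", call. = FALSE)
  check_symmetric(counts)
  if (n > 1) {
    steps <- diff(x$bin_starts)
    if (any(steps != x$bin_size)) {
      stop("bin_starts must ascend with uniform spacing equal to bin_size",
           call. = FALSE)
    }
  }
  invisible(x)
}

# symmetry to 1e-9 relative tolerance (exact for integer-valued input)
check_symmetric <- function(m, tol = 1e-9) {
  d <- max(abs(m - t(m)))
  scale <- max(abs(m), 1)
  if (d > tol * scale) {
    stop("matrix is not symmetric (max asymmetry ", format(d), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins of %d bp%s, %d masked\n",
              x$chrom, n_bins(x), x$bin_size,
              if (x$balanced) " (ICE-balanced)" else "", sum(x$mask)))
  cat(sprintf("  total counts: %.6g\n", sum(x$counts)))
  invisible(x)
}
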