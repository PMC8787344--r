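#' ICE matrix balancing
#'
#' Iterative correction (ICE) equalizes the marginal sums of a symmetric
#' contact matrix to remove coverage bias. Bins whose nonzero marginal sum
#' falls in the lowest `low_coverage_fraction` quantile, together with
#' all-zero bins, are masked (rows and columns zeroed and flagged) before
#' balancing, since iterative correction diverges on near-empty rows. Over
#' the unmasked bins the bias vector is updated multiplicatively from the
#' marginal ratio (`b <- b * sqrt(marginal / mean(marginal))`; rows and
#' columns of a symmetric matrix share one bias, so the symmetric
#' square-root correction is applied per sweep) until the coefficient of
#' variation of the unmasked marginals drops below `tol` or `max_iter`
#' sweeps are reached. The output is rescaled so its total equals the input
#' total over unmasked entries.
#'
#' @param matrix A symmetric, non-negative [contact_matrix()].
#' @param max_iter Maximum balancing sweeps (default 100).
#' @param tol Target coefficient of variation of unmasked marginals
#'   (default 1e-5).
#' @param low_coverage_fraction Fraction of lowest-coverage nonzero bins to
#'   mask (default 0.02).
#' @return A balanced [contact_matrix()] with `balanced = TRUE` and masked
#'   bins recorded in `$mask`.
#' @examples
#' m <- contact_matrix(matrix(c(4, 2, 2, 6), 2), "chr1")
#' b <- ice_normalize(m)
#' rowSums(b$counts)  # equalized marginals
#' @export
ice_normalize <- function(matrix, max_iter = 100L, tol = 1e-5,
                          low_coverage_fraction = 0.02) {
  stopifnot(is_contact_matrix(matrix))
  w <- matrix$counts
  check_symmetric(w)
  marg <- rowSums(w)
  mask <- matrix$mask | marg == 0
  nz <- marg[!mask]
  if (length(nz) > 0 && low_coverage_fraction > 0) {
    cutoff <- stats::quantile(nz, low_coverage_fraction, names = FALSE,
                              type = 7)
    # strictly-below cut keeps uniform matrices intact
    mask <- mask | (marg < cutoff & !mask)
  }
  keep <- which(!mask)
  if (length(keep) < 2) {
    stop("fewer than 2 unmasked bins: degenerate input for ICE",
         call. = FALSE)
  }
  w[mask, ] <- 0
  w[, mask] <- 0
  total_in <- sum(w)

  sub <- w[keep, keep, drop = FALSE]
  for (iter in seq_len(max_iter)) {
    m <- rowSums(sub)
    mu <- mean(m)
    cv <- stats::sd(m) / mu
    if (!is.finite(cv) || cv < tol) break
    # symmetric proportional scaling: because rows and columns share the
    # same bias on a symmetric matrix, each sweep corrects by the square
    # root of the marginal ratio (plain division over-corrects and
    # converges far more slowly)
    s <- sqrt(m / mu)
    sub <- sub / outer(s, s)
  }
  m <- rowSums(sub)
  if (stats::sd(m) / mean(m) >= tol) {
    warning("ICE did not reach target marginal CV within max_iter sweeps")
  }
  sub <- sub * (total_in / sum(sub))
  sub <- (sub + t(sub)) / 2   # symmetry to machine precision
  out <- w * 0
  out[keep, keep] <- sub
  contact_matrix(out, chrom = matrix$chrom, bin_size = matrix$bin_size,
                 bin_starts = matrix$bin_starts, balanced = TRUE,
                 mask = mask)
}
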