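#' Network-enhancement configuration
#'
#' Parameters of the graph-diffusion denoiser. `k_neighbors` controls the
#' sparsified local kernel (each bin keeps only its strongest neighbors),
#' `diffusion_weight` is the retention weight `a` of the diffusion
#' recursion `W <- a * T W T + (1 - a) * T`. The closed-form mode applies
#' the equivalent eigenvalue map `lambda -> (1 - a) lambda / (1 - a lambda^2)`
#' of the doubly-stochastic kernel `T`; the iterative mode runs the
#' recursion itself and is retained as an independent cross-check.
#'
#' @param k_neighbors Number of nearest neighbors kept per bin (default
#'   `min(20, n - 1)`, resolved against the matrix at call time when `NULL`).
#' @param diffusion_weight Diffusion retention weight in (0, 1); default 0.9.
#' @param mode `"closed_form"` (default) or `"iterative"`.
#' @param max_iter Maximum iterations in iterative mode (default 50).
#' @param tol Relative Frobenius-change stopping tolerance in iterative mode
#'   (default 1e-6).
#' @return A list of class `NEConfig`.
#' @export
ne_config <- function(k_neighbors = NULL, diffusion_weight = 0.9,
                      mode = c("closed_form", "iterative"),
                      max_iter = 50L, tol = 1e-6) {
  mode <- match.arg(mode)
  if (diffusion_weight <= 0 || diffusion_weight >= 1) {
    stop("diffusion_weight must lie in (0, 1)", call. = FALSE)
  }
  structure(list(k_neighbors = k_neighbors,
                 diffusion_weight = diffusion_weight, mode = mode,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "NEConfig")
}

#' K-nearest-neighbor localization of a contact matrix
#'
#' Builds the row-stochastic localized kernel `P`: row `i` keeps only the
#' `k_neighbors` largest off-diagonal weights of row `i` (ties broken by
#' lower column index) and is normalized to sum to one. Rows with no
#' nonzero off-diagonal weight become zero rows and are flagged in the
#' `"zero_rows"` attribute.
#'
#' @param matrix A symmetric non-negative [contact_matrix()] (or plain
#'   square matrix) with zero diagonal.
#' @param k_neighbors Number of neighbors to keep, in `[1, n - 1]`.
#' @return An `n x n` non-negative matrix with row sums in `{0, 1}`.
#' @export
knn_localize <- function(matrix, k_neighbors) {
  w <- if (is_contact_matrix(matrix)) matrix$counts else as.matrix(matrix)
  n <- nrow(w)
  if (k_neighbors < 1 || k_neighbors >= n) {
    stop("k_neighbors must satisfy 1 <= k < n_bins", call. = FALSE)
  }
  p <- base::matrix(0, n, n)
  zero_rows <- logical(n)
  for (i in seq_len(n)) {
    row <- w[i, ]
    row[i] <- 0
    if (all(row == 0)) {
      zero_rows[i] <- TRUE
      next
    }
    # stable order: decreasing weight, ties to the lower column index
    ord <- order(-row, seq_along(row))
    keep <- ord[seq_len(k_neighbors)]
    keep <- keep[row[keep] > 0]
    p[i, keep] <- row[keep] / sum(row[keep])
  }
  attr(p, "zero_rows") <- zero_rows
  p
}

# symmetric doubly-stochastic kernel T[i,j] = sum_v P[i,v] P[j,v] / colsum(P)[v]
ne_kernel <- function(p) {
  cs <- colSums(p)
  pos <- cs > 0
  ps <- p[, pos, drop = FALSE]
  tk <- ps %*% (t(ps) / cs[pos])
  (tk + t(tk)) / 2
}

#' Network enhancement of a contact matrix
#'
#' Graph-diffusion denoising: edge weights that are supported by strong
#' neighboring edges are strengthened and poorly supported edges are
#' weakened. The localized row-stochastic kernel `P` from [knn_localize()]
#' is turned into the symmetric doubly-stochastic transition kernel
#' `T[i, j] = sum_v P[i, v] P[j, v] / sum_u P[u, v]`, which is then
#' diffused either by iterating `W <- a T W T + (1 - a) T` from `W = T`
#' (iterative mode) or by mapping each eigenvalue `lambda` of `T` to
#' `(1 - a) lambda / (1 - a lambda^2)` while keeping the eigenvectors
#' (closed form; the fixed point of the same recursion). The result is
#' symmetrized, clipped at zero, and its diagonal zeroed. The diagonal of
#' the input is ignored (self-loops would otherwise dominate neighbor
#' selection at short genomic distances) and masked bins stay zero.
#'
#' @param matrix A symmetric, non-negative [contact_matrix()].
#' @param config An [ne_config()].
#' @return An enhanced [contact_matrix()] with the same bin metadata.
#' @examples
#' m <- contact_matrix(matrix(c(0, 8, 1, 8, 0, 1, 1, 1, 0), 3), "chr1")
#' e <- network_enhance(m, ne_config(k_neighbors = 2))
#' @export
network_enhance <- function(matrix, config = ne_config()) {
  stopifnot(is_contact_matrix(matrix), inherits(config, "NEConfig"))
  w <- matrix$counts
  check_symmetric(w)
  diag(w) <- 0
  n <- nrow(w)
  k <- config$k_neighbors
  if (is.null(k)) k <- min(20L, n - 1L)
  p <- knn_localize(w, k)
  tk <- ne_kernel(p)
  a <- config$diffusion_weight

  if (config$mode == "iterative") {
    wd <- tk
    for (iter in seq_len(config$max_iter)) {
      wn <- a * (tk %*% wd %*% tk) + (1 - a) * tk
      delta <- norm(wn - wd, "F") / max(norm(wd, "F"), .Machine$double.eps)
      wd <- wn
      if (delta < config$tol) break
    }
  } else {
    eg <- eigen(tk, symmetric = TRUE)
    lam <- pmin(eg$values, 1 - 1e-12)   # guard the 1 - a*lambda^2 denominator
    lam <- pmax(lam, -(1 - 1e-12))
    fl <- (1 - a) * lam / (1 - a * lam^2)
    wd <- eg$vectors %*% (fl * t(eg$vectors))
  }

  wd <- (wd + t(wd)) / 2
  wd[wd < 0] <- 0
  diag(wd) <- 0
  if (any(matrix$mask)) {
    wd[matrix$mask, ] <- 0
    wd[, matrix$mask] <- 0
  }
  contact_matrix(wd, chrom = matrix$chrom, bin_size = matrix$bin_size,
                 bin_starts = matrix$bin_starts, balanced = matrix$balanced,
                 mask = matrix$mask)
}
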