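#' Choose the factorization rank from chromosome length
#'
#' The rank `k` (number of latent factors, equal to the number of clusters)
#' is set so that the expected genomic span of each cluster is about
#' `target_cluster_span` (1 Mb by default, the typical scale of
#' topologically associating domains): `k = max(2, round(n * bin_size /
#' target_cluster_span))`.
#'
#' @param n_bins Number of bins on the chromosome.
#' @param bin_size Bin width in bp.
#' @param target_cluster_span Expected cluster span in bp (default 1e6).
#' @return Integer rank `k >= 2`.
#' @examples
#' choose_rank(1000, 10000)  # 10 Mb chromosome -> k = 10
#' @export
choose_rank <- function(n_bins, bin_size, target_cluster_span = 1e6) {
  stopifnot(n_bins >= 2)
  max(2L, as.integer(round(n_bins * bin_size / target_cluster_span)))
}

#' Multiview NMF objective value
#'
#' The consensus-regularized objective
#' `sum_t || X(t) - U(t) V(t)^T ||_F^2 + alpha * || V(t) - V(c) ||_F^2`.
#'
#' @param X List of [contact_matrix()] objects (or plain matrices), one per
#'   task.
#' @param factors A `FactorSet` as returned by [mvnmf_fit()], or any list
#'   with elements `U`, `V` (lists of matrices), `V_consensus`, `alpha`.
#' @return A single non-negative number.
#' @export
mvnmf_objective <- function(X, factors) {
  Xm <- lapply(X, function(x) if (is_contact_matrix(x)) x$counts else as.matrix(x))
  tt <- length(Xm)
  if (tt != length(factors$U) || tt != length(factors$V)) {
    stop("number of tasks in X and factors differ", call. = FALSE)
  }
  obj <- 0
  for (t in seq_len(tt)) {
    u <- factors$U[[t]]; v <- factors$V[[t]]
    if (nrow(Xm[[t]]) != nrow(u) || ncol(Xm[[t]]) != nrow(v)) {
      stop("factor dimensions do not match X", call. = FALSE)
    }
    obj <- obj + sum((Xm[[t]] - u %*% t(v))^2) +
      factors$alpha * sum((v - factors$V_consensus)^2)
  }
  obj
}

# seeded uniform init on [0, s], s = sqrt(mean(X)/k); one RNG stream per task
# so that the alpha = 0 factorization is reproducible as independent
# single-task runs with seeds seed, seed + 1, ...
init_factors <- function(x, k, seed) {
  set.seed(seed)
  n <- nrow(x)
  s <- sqrt(max(mean(x), .Machine$double.eps) / k)
  list(U = matrix(stats::runif(n * k, 0, s), n, k),
       V = matrix(stats::runif(n * k, 0, s), n, k))
}

# One HALS sweep over the columns of U (X ~ U V^T):
#   u_j <- max(eps, u_j + (X v_j - U (V^T v_j)) / (v_j^T v_j))
hals_update_u <- function(u, v, x, eps) {
  xv <- x %*% v
  vtv <- crossprod(v)
  k <- ncol(u)
  for (j in seq_len(k)) {
    denom <- vtv[j, j]
    if (denom < 1e-12) {
      u[, j] <- reseed_column(x - u %*% t(v), eps)
      next
    }
    uj <- u[, j] + (xv[, j] - u %*% vtv[, j]) / denom
    u[, j] <- pmax(eps, uj)
  }
  u
}

# One HALS sweep over the columns of V with the consensus pull:
#   v_j <- max(eps, (X^T u_j - V (U^T u_j) + v_j (u_j^T u_j) + alpha v_cj)
#                   / (u_j^T u_j + alpha))
hals_update_v <- function(v, u, x, vc, alpha, eps) {
  xtu <- crossprod(x, u)
  utu <- crossprod(u)
  k <- ncol(v)
  for (j in seq_len(k)) {
    denom <- utu[j, j] + alpha
    if (denom < 1e-12) {
      v[, j] <- reseed_column(x - u %*% t(v), eps)
      next
    }
    num <- xtu[, j] - v %*% utu[, j] + v[, j] * utu[j, j] + alpha * vc[, j]
    v[, j] <- pmax(eps, num / denom)
  }
  v
}

# a dead column (norm below ~1e-12) is reseeded from the residual's
# largest-magnitude row, at a tiny scale so the objective is not perturbed
reseed_column <- function(resid, eps) {
  i <- which.max(rowSums(abs(resid)))
  dir <- pmax(abs(resid[i, ]), eps)
  1e-8 * dir / max(dir)
}

#' Fit a consensus-regularized multiview NMF by HALS
#'
#' Jointly factorizes `T >= 2` symmetric non-negative matrices `X(t)` as
#' `U(t) V(t)^T` while pulling every `V(t)` toward a shared consensus
#' factor `V(c)`, by minimizing
#' `sum_t ||X(t) - U(t) V(t)^T||_F^2 + alpha ||V(t) - V(c)||_F^2`.
#' The solver is hierarchical alternating least squares (HALS): each sweep
#' performs exact non-negative coordinate updates column by column for every
#' `U(t)` and `V(t)`, then the closed-form consensus update
#' `V(c) <- mean_t V(t)` (the unconstrained minimizer, automatically
#' non-negative). Each update solves its subproblem exactly, so the
#' objective trace is non-increasing and the iteration converges to a local
#' minimum. Factors are floored at `eps = 1e-16` rather than zero to avoid
#' dead columns. All-zero (masked) bins carry no signal; their factor rows
#' stay at the floor and downstream cluster assignment reports them
#' unassigned.
#'
#' @param X List of symmetric, non-negative [contact_matrix()] objects (or
#'   plain matrices) of identical dimension, one per task.
#' @param rank Number of latent factors `k < n` (see [choose_rank()]).
#' @param alpha Consensus regularization weight, `>= 0`.
#' @param max_iter Maximum HALS sweeps (default 300).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param seed Integer seed; task `t` is initialized from RNG stream
#'   `seed + t - 1` with entries uniform on `[0, sqrt(mean(X(t))/k)]`.
#' @return A `FactorSet`: list with `U`, `V` (lists of `n x k` matrices),
#'   `V_consensus`, `rank`, `alpha`, `objective_trace`, `seed`, `mask`.
#' @examples
#' w <- c(1, 2, 3)
#' X <- list(w %o% w, w %o% w)
#' f <- mvnmf_fit(X, rank = 1, alpha = 1, seed = 1)
#' tail(f$objective_trace, 1)
#' @export
mvnmf_fit <- function(X, rank, alpha, max_iter = 300L, tol = 1e-6,
                      seed = 13L) {
  Xm <- lapply(X, function(x) if (is_contact_matrix(x)) x$counts else as.matrix(x))
  tt <- length(Xm)
  stopifnot(tt >= 1)
  n <- nrow(Xm[[1]])
  if (rank >= n) stop("rank must be smaller than the matrix dimension",
                      call. = FALSE)
  for (x in Xm) {
    if (nrow(x) != n || ncol(x) != n) {
      stop("all task matrices must share the same dimension", call. = FALSE)
    }
    if (any(x < 0)) stop("task matrices must be non-negative", call. = FALSE)
  }
  eps <- 1e-16
  k <- as.integer(rank)
  mask <- Reduce(`&`, lapply(Xm, function(x) rowSums(x) == 0))

  fac <- lapply(seq_len(tt), function(t) init_factors(Xm[[t]], k, seed + t - 1L))
  U <- lapply(fac, `[[`, "U")
  V <- lapply(fac, `[[`, "V")
  vc <- Reduce(`+`, V) / tt

  fs <- list(U = U, V = V, V_consensus = vc, alpha = alpha)
  trace <- mvnmf_objective(Xm, fs)
  for (iter in seq_len(max_iter)) {
    for (t in seq_len(tt)) {
      U[[t]] <- hals_update_u(U[[t]], V[[t]], Xm[[t]], eps)
      V[[t]] <- hals_update_v(V[[t]], U[[t]], Xm[[t]], vc, alpha, eps)
    }
    vc <- Reduce(`+`, V) / tt
    fs <- list(U = U, V = V, V_consensus = vc, alpha = alpha)
    obj <- mvnmf_objective(Xm, fs)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - obj) <= tol * max(prev, .Machine$double.eps)) break
  }
  structure(list(U = U, V = V, V_consensus = vc, rank = k, alpha = alpha,
                 tasks = tt, objective_trace = trace, seed = seed,
                 mask = mask),
            class = "FactorSet")
}

#' Single-task HALS NMF
#'
#' Plain non-negative factorization `X ~ U V^T` with the same column-wise
#' HALS updates, initialization, and stopping rule as [mvnmf_fit()] but no
#' consensus coupling. `mvnmf_fit()` with `alpha = 0` reproduces this
#' function task by task (task `t` corresponds to seed `seed + t - 1`).
#'
#' @inheritParams mvnmf_fit
#' @param X A symmetric non-negative matrix or [contact_matrix()].
#' @return List with `U`, `V`, `objective_trace`, `seed`.
#' @export
nmf_hals <- function(X, rank, max_iter = 300L, tol = 1e-6, seed = 13L) {
  x <- if (is_contact_matrix(X)) X$counts else as.matrix(X)
  if (any(x < 0)) stop("X must be non-negative", call. = FALSE)
  if (rank >= nrow(x)) stop("rank must be smaller than the matrix dimension",
                            call. = FALSE)
  eps <- 1e-16
  fac <- init_factors(x, rank, seed)
  u <- fac$U; v <- fac$V
  zero_vc <- matrix(0, nrow(x), rank)
  trace <- sum((x - u %*% t(v))^2)
  for (iter in seq_len(max_iter)) {
    u <- hals_update_u(u, v, x, eps)
    v <- hals_update_v(v, u, x, zero_vc, 0, eps)
    obj <- sum((x - u %*% t(v))^2)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (abs(prev - obj) <= tol * max(prev, .Machine$double.eps)) break
  }
  list(U = u, V = v, objective_trace = trace, seed = seed)
}

#' @export
print.FactorSet <- function(x, ...) {
  cat(sprintf("FactorSet: %d tasks, n = %d, k = %d, alpha = %g\n",
              x$tasks, nrow(x$U[[1]]), x$rank, x$alpha))
  cat(sprintf("  %d sweeps, objective %.6g -> %.6g\n",
              length(x$objective_trace) - 1L, x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
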