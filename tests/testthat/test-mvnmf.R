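test_that("choose_rank targets ~1 Mb clusters with a floor of 2", {
  expect_equal(choose_rank(1000, 10000), 10L)
  expect_equal(choose_rank(5, 10000), 2L)
  expect_equal(choose_rank(28200, 10000), 282L)
})

test_that("objective matches a term-by-term summation oracle", {
  set.seed(21)
  X <- lapply(1:2, function(i) random_symmetric_pois(8, 6, 20 + i))
  U <- lapply(1:2, function(i) matrix(runif(8 * 3), 8))
  V <- lapply(1:2, function(i) matrix(runif(8 * 3), 8))
  Vc <- matrix(runif(8 * 3), 8)
  fs <- list(U = U, V = V, V_consensus = Vc, alpha = 3)
  expect_equal(mvnmf_objective(X, fs), oracle_objective(X, U, V, Vc, 3))

  exact <- list(U = U, V = U, V_consensus = U[[1]], alpha = 3)
  Xe <- lapply(U, function(u) u %*% t(u))
  exact$V_consensus <- (U[[1]] + U[[2]]) / 2
  expect_gt(mvnmf_objective(Xe, exact), 0)   # consensus term alone
  same <- list(U = list(U[[1]], U[[1]]), V = list(U[[1]], U[[1]]),
               V_consensus = U[[1]], alpha = 3)
  expect_equal(mvnmf_objective(list(U[[1]] %*% t(U[[1]]),
                                    U[[1]] %*% t(U[[1]])), same), 0)
})

test_that("exact rank-1 input is recovered to numerical zero", {
  w <- c(1, 2, 3)
  X <- list(w %o% w, w %o% w)
  f <- mvnmf_fit(X, rank = 1, alpha = 1, max_iter = 2000, tol = 0, seed = 1)
  expect_lt(f$objective_trace[length(f$objective_trace)], 1e-8)
  expect_lt(max(abs(f$U[[1]] %*% t(f$V[[1]]) - X[[1]])), 1e-4)
})

test_that("alpha = 0 reduces to independent single-task HALS runs", {
  x1 <- random_symmetric_pois(8, 10, 31)
  x2 <- random_symmetric_pois(8, 10, 32)
  f <- mvnmf_fit(list(x1, x2), rank = 3, alpha = 0, max_iter = 50, tol = 0,
                 seed = 7)
  s1 <- nmf_hals(x1, 3, max_iter = 50, tol = 0, seed = 7)
  s2 <- nmf_hals(x2, 3, max_iter = 50, tol = 0, seed = 8)
  expect_lt(max(abs(f$U[[1]] - s1$U)), 1e-10)
  expect_lt(max(abs(f$V[[1]] - s1$V)), 1e-10)
  expect_lt(max(abs(f$U[[2]] - s2$U)), 1e-10)
  expect_lt(max(abs(f$V[[2]] - s2$V)), 1e-10)
})

test_that("large alpha forces the task V factors into consensus", {
  xa <- planted_two_domain(20, depth = 10, seed = 41)
  xb <- planted_two_domain(20, depth = 10, seed = 42)
  f <- mvnmf_fit(list(xa, xb), rank = 2, alpha = 1e8, max_iter = 300,
                 tol = 1e-10, seed = 4)
  expect_lt(norm(f$V[[1]] - f$V[[2]], "F") / norm(f$V[[1]], "F"), 1e-2)
})

test_that("objective trace is non-increasing across random instances", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(6:30, 1)
    k <- sample(2:5, 1)
    alpha <- sample(c(0, 1, 1e4), 1)
    X <- list(random_symmetric_pois(n, 8, s * 2),
              random_symmetric_pois(n, 8, s * 2 + 1))
    f <- mvnmf_fit(X, k, alpha, max_iter = 40, tol = 0, seed = s)
    expect_true(all(diff(f$objective_trace) <= 1e-8))
    for (t in 1:2) {
      expect_true(all(f$U[[t]] >= 0))
      expect_true(all(f$V[[t]] >= 0))
    }
  }
})

test_that("the consensus update is the exact minimizer given the tasks", {
  set.seed(51)
  V <- list(matrix(runif(8), 4, 2), matrix(runif(8), 4, 2))
  vc_impl <- (V[[1]] + V[[2]]) / 2
  # numeric oracle: minimize the consensus term entrywise with optimize()
  vc_oracle <- vc_impl * NA
  for (i in 1:4) for (j in 1:2) {
    vc_oracle[i, j] <- stats::optimize(function(v) {
      (V[[1]][i, j] - v)^2 + (V[[2]][i, j] - v)^2
    }, c(-10, 10))$minimum
  }
  expect_equal(vc_impl, vc_oracle, tolerance = 1e-6)

  # and a fitted model keeps V_consensus at the task mean
  X <- list(random_symmetric_pois(10, 10, 52), random_symmetric_pois(10, 10, 53))
  f <- mvnmf_fit(X, 2, alpha = 10, max_iter = 30, seed = 5)
  expect_lt(max(abs(f$V_consensus - (f$V[[1]] + f$V[[2]]) / 2)), 1e-10)
})

test_that("fit validates rank and non-negativity", {
  x <- random_symmetric_pois(5, 5, 61)
  expect_error(mvnmf_fit(list(x, x), rank = 5, alpha = 1), "rank")
  bad <- x; bad[1, 2] <- bad[2, 1] <- -1
  expect_error(mvnmf_fit(list(bad, x), rank = 2, alpha = 1), "non-negative")
  expect_error(mvnmf_fit(list(x, x[1:4, 1:4]), rank = 2, alpha = 1),
               "same dimension")
})

test_that("clusterings are stable across initialization seeds", {
  sim <- generate_pair(synthetic_spec(n_bins = 120, seed = 9,
                                      domain_boundaries = c(41L, 81L),
                                      reassigned_segments =
                                        list(c(41L, 50L, 1L))))
  labs <- lapply(1:5, function(s) {
    f <- mvnmf_fit(list(sim$A, sim$B), rank = 3, alpha = scale_alpha(
      list(sim$A, sim$B)), max_iter = 150, seed = s)
    c(assign_clusters(f, 1)$labels, assign_clusters(f, 2)$labels)
  })
  pr <- utils::combn(5, 2, function(ij) rand_index(labs[[ij[1]]],
                                                   labs[[ij[2]]]))
  expect_gte(mean(pr), 0.85)
})
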