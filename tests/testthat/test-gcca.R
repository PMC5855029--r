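test_that("within-class scatter matches its defining sum", {
  X <- rbind(c(0, 0), c(2, 0))
  expect_equal(within_class_scatter(X, c(1, 1)), diag(c(2, 0)))
  pv <- make_paired_views(seed = 2)
  S <- within_class_scatter(pv$X, pv$y)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  # shifting one class leaves it unchanged
  X2 <- pv$X
  X2[pv$y == 1, ] <- X2[pv$y == 1, ] + 7
  expect_equal(within_class_scatter(X2, pv$y), S)
  # samples equal to their class mean give the zero matrix
  M0 <- rbind(c(1, 2), c(1, 2), c(5, 1), c(5, 1))
  expect_equal(within_class_scatter(M0, c(1, 1, 2, 2)), matrix(0, 2, 2))
  expect_error(within_class_scatter(pv$X, pv$y[-1]), "does not match")
})

test_that("between-set covariance is the paired cross-covariance", {
  set.seed(5)
  X <- matrix(stats::rnorm(60), 20, 3)
  C_self <- between_set_covariance(X, X)
  expect_equal(C_self, crossprod(scale(X, scale = FALSE)) / 20)
  Y <- matrix(stats::rnorm(60), 20, 3)
  expect_equal(between_set_covariance(X, Y),
               t(between_set_covariance(Y, X)))
  set.seed(6)
  A <- matrix(stats::rnorm(3e4), ncol = 3)
  B <- matrix(stats::rnorm(3e4), ncol = 3)
  expect_lt(max(abs(between_set_covariance(A, B))), 0.05)
  expect_error(between_set_covariance(A, B[-1, ]), "paired")
})

test_that("the class-aware solver attains the brute-force criterion optimum", {
  pv <- make_paired_views(seed = 7)
  P <- solve_gcca(pv$X, pv$Y, pv$y, ridge = 0)
  Swx <- within_class_scatter(pv$X, pv$y)
  Swy <- within_class_scatter(pv$Y, pv$y)
  C <- between_set_covariance(pv$X, pv$Y)
  # normalisation and criterion consistency
  expect_equal(drop(crossprod(P$U[, 1], Swx %*% P$U[, 1])), 1,
               tolerance = 1e-10)
  expect_equal(drop(crossprod(P$U[, 1], C %*% P$V[, 1])),
               P$correlations[1], tolerance = 1e-10)
  expect_true(all(diff(P$correlations) <= 1e-10))
  # sign convention
  expect_true(all(apply(P$U, 2, function(u) u[which.max(abs(u))] > 0)))
  # brute force with random restarts + refinement
  best <- brute_force_gcca(Swx, Swy, C, n_restarts = 5000, seed = 7)
  expect_equal(P$correlations[1], best, tolerance = 1e-6)
})

test_that("singular scatter without ridge names the remedy", {
  set.seed(8)
  X <- cbind(stats::rnorm(12), 0)     # zero-variance column
  y <- rep(1:2, each = 6)
  expect_error(solve_gcca(X, X, y, ridge = 0), "ridge")
})

test_that("classical CCA matches stats::cancor and its identities", {
  set.seed(9)
  X <- matrix(stats::rnorm(600), 200, 3)
  P_self <- solve_cca(X, X)
  expect_equal(P_self$correlations, rep(1, 3), tolerance = 1e-8)
  A <- matrix(stats::rnorm(9), 3, 3)
  P_map <- solve_cca(X, X %*% A)
  expect_equal(P_map$correlations, rep(1, 3), tolerance = 1e-8)
  Y <- matrix(stats::rnorm(3000), 1000, 3)
  X2 <- matrix(stats::rnorm(3000), 1000, 3)
  expect_lt(solve_cca(X2, Y)$correlations[1], 0.2)
  cc <- stats::cancor(X2, Y)
  expect_equal(solve_cca(X2, Y)$correlations, cc$cor, tolerance = 1e-8)
})

test_that("projection and fusion follow the stated algebra", {
  pv <- make_paired_views(seed = 10)
  P <- solve_gcca(pv$X, pv$Y, pv$y)
  pr <- project(pv$X, pv$Y, P)
  expect_equal(dim(pr$Xs), c(nrow(pv$X), P$d))
  pr2 <- project(2 * pv$X, pv$Y, P)
  expect_equal(pr2$Xs, 2 * pr$Xs)
  Z1 <- fuse(pr$Xs, pr$Ys, "type1")
  Z2 <- fuse(pr$Xs, pr$Ys, "type2")
  expect_equal(ncol(Z1), 2 * ncol(Z2))
  expect_equal(fuse(pr$Xs, -pr$Xs, "type2"),
               matrix(0, nrow(pr$Xs), ncol(pr$Xs)), ignore_attr = TRUE)
  Xs <- rbind(c(1, 2), c(3, 4))
  Ys <- rbind(c(10, 20), c(30, 40))
  expect_equal(fuse(Xs, Ys, "type2"), rbind(c(11, 22), c(33, 44)),
               ignore_attr = TRUE)
  expect_error(fuse(Xs, Ys[1, , drop = FALSE]), "identical shape")
})

test_that("multiset fusion is consistent with the two-set solver", {
  pv <- make_paired_views(seed = 12)
  ridge <- 1e-4
  P2 <- solve_gcca(pv$X, pv$Y, pv$y, ridge = ridge)
  for (strat in c("sumcor", "pairwise")) {
    M <- multiset_gcca(list(pv$X, pv$Y), pv$y, ridge = ridge,
                       strategy = strat)
    expect_equal(M$correlations[1], P2$correlations[1], tolerance = 1e-8)
  }
  # three duplicated sets: every pairwise criterion equals the
  # self-criterion of the two-set solver
  Pself <- solve_gcca(pv$X, pv$X, pv$y, ridge = ridge)
  M3 <- multiset_gcca(list(pv$X, pv$X, pv$X), pv$y, ridge = ridge)
  expect_equal(M3$correlations[1] / 3, Pself$correlations[1],
               tolerance = 1e-6)
  # the fitted transform replays exactly on the training sets
  expect_equal(apply_multiset(M3, list(pv$X, pv$X, pv$X)), M3$fused)
  expect_error(multiset_gcca(list(pv$X), pv$y), ">= 2")
})

test_that("the sumcor objective dominates single pairwise criteria", {
  set.seed(14)
  n <- 60
  y <- rep(1:3, each = 20)
  base <- matrix(stats::rnorm(n * 3), n, 3)
  sets <- lapply(1:4, function(i)
    base + matrix(stats::rnorm(n * 3), n, 3) * 0.7 + outer(y, 1:3) * 0.2)
  M <- multiset_gcca(sets, y, ridge = 1e-4)
  pair_tops <- c()
  for (i in 1:3) for (j in (i + 1):4)
    pair_tops <- c(pair_tops,
                   solve_gcca(sets[[i]], sets[[j]], y,
                              ridge = 1e-4)$correlations[1])
  expect_gte(M$correlations[1] + 1e-8, max(pair_tops))
})
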