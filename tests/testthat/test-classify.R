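test_that("the RBF kernel matches its closed form", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 2), 1)
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), 5), exp(-1))
  expect_equal(rbf_kernel(x, x + 1, 1.7), rbf_kernel(x + 1, x, 1.7))
  expect_error(rbf_kernel(x, x, 0), "positive")
})

test_that("sensitivity/specificity follow the one-vs-rest definitions", {
  conf <- diag(c(10, 20, 30))
  ss <- sen_spe(conf)
  expect_equal(unname(ss[, "sen"]), rep(1, 3))
  expect_equal(unname(ss[, "spe"]), rep(1, 3))
  ss2 <- sen_spe(rbind(c(8, 2), c(1, 9)))
  expect_equal(unname(ss2[1, ]), c(0.8, 0.9))
  # a class whose diagonal share is 97.5% of its row has SEN 97.5%
  conf3 <- rbind(c(39, 1), c(0, 40))     # 39/40 = 97.5%
  expect_equal(unname(sen_spe(conf3)[1, "sen"]), 0.975)
  expect_error(sen_spe(matrix(1, 2, 3)), "square")
  expect_error(sen_spe(rbind(c(0, 0), c(1, 5))), "empty")
})

test_that("cross-validation is stratified, exact on separated classes", {
  b <- make_blobs(12, 8, d = 4, sep = 15, seed = 17)
  cv <- crossval(b$X, b$y, k = 6, seed = 3)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(sum(cv$confusion), 96)
  expect_equal(unname(rowSums(cv$confusion)), rep(12, 8))
  sizes <- vapply(cv$folds, function(f) length(f$test_idx), integer(1))
  expect_lte(diff(range(sizes)), 1)
  small <- make_blobs(5, 4, d = 2, sep = 8, seed = 22)
  expect_error(crossval(small$X, small$y, k = 6), "smaller k")
})

test_that("label-shuffled data scores at chance", {
  b <- make_blobs(50, 8, d = 4, sep = 15, seed = 18)
  set.seed(19)
  cv <- crossval(b$X, sample(b$y), k = 6, seed = 4)
  expect_lt(abs(cv$mean_accuracy - 1 / 8), 0.05)
})

test_that("PSO tuning improves on a deliberately bad kernel width", {
  b <- make_blobs(15, 4, d = 3, sep = 4, seed = 20)
  Z <- scale(b$X)
  cfg <- pso_config(swarm_size = 8, iterations = 6, seed = 5)
  tune <- pso_tune(Z, b$y, cfg)
  expect_true(all(diff(tune$trace) >= 0))
  sig0 <- median_sigma <- semgfusion:::median_heuristic_sigma(Z)
  expect_gte(log10(tune$sigma), log10(median_sigma) - 2 - 1e-9)
  expect_lte(log10(tune$sigma), log10(median_sigma) + 2 + 1e-9)
  tune2 <- pso_tune(Z, b$y, cfg)
  expect_identical(tune, tune2)
  # inner-CV accuracy of the tuned pair is at least that of a width far
  # outside the useful range
  folds <- semgfusion:::stratified_folds(b$y, 3, seed = 5)
  bad <- semgfusion:::inner_cv_accuracy(Z, b$y, 100 * median_sigma, 10,
                                        folds)
  expect_gte(tune$accuracy, bad)
})

test_that("PSO validates its bounds", {
  expect_error(pso_config(sigma_bounds = c(1, 1)), "empty")
})
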