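test_that("fuzzy c-means satisfies its contract on simple geometries", {
  set.seed(41)
  Z <- matrix(stats::rnorm(60), 30, 2)
  f1 <- fcm(Z, 1, seed = 2)
  expect_equal(drop(f1$centers), colMeans(Z), tolerance = 1e-6)
  expect_true(all(f1$memberships == 1))
  b <- make_blobs(25, 2, d = 2, sep = 20, seed = 3)
  f2 <- fcm(b$X, 2, seed = 4)
  agreement <- max(mean(f2$hard_labels == as.integer(b$y)),
                   mean(f2$hard_labels == 3 - as.integer(b$y)))
  expect_equal(agreement, 1)
  expect_equal(rowSums(f2$memberships), rep(1, 50), tolerance = 1e-12)
  expect_error(fcm(Z, 31), "cannot form")
})

test_that("the FCM objective trace never increases (20 seeded runs)", {
  b <- make_blobs(15, 4, d = 3, sep = 3, seed = 6)
  for (s in 1:20) {
    f <- fcm(b$X, 4, seed = s)
    expect_true(all(diff(f$objective_trace) <= 1e-8 *
                      max(1, f$objective_trace[1])))
  }
})

test_that("our FCM agrees with e1071::cmeans on separated blobs", {
  b <- make_blobs(20, 3, d = 2, sep = 15, seed = 7)
  f <- fcm(b$X, 3, seed = 8)
  cm <- e1071::cmeans(b$X, 3, m = 2)
  ord <- function(M) M[order(M[, 1]), ]
  expect_equal(ord(f$centers), ord(cm$centers), tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("Davies-Bouldin index matches hand evaluation and invariances", {
  Z <- rbind(c(-1, 0), c(1, 0), c(9, 0), c(11, 0))
  lab <- c(1, 1, 2, 2)
  r <- dbi(Z, lab)
  expect_equal(r$value, 0.2)
  expect_equal(r$S, c(1, 1))
  # zero-dispersion clusters at distinct centres
  expect_equal(dbi(rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5)), lab)$value, 0)
  # duplicating every point changes nothing
  expect_equal(dbi(rbind(Z, Z), c(lab, lab))$value, 0.2)
  # global rescaling changes nothing
  expect_equal(dbi(17 * Z, lab)$value, 0.2)
  expect_error(dbi(Z, factor(lab, levels = 1:3)), "empty")
  expect_error(dbi(Z, rep(1, 4)), "K >= 2")
})

test_that("the DBI sweep finds the true cluster count of 8 blobs", {
  b <- make_blobs(15, 8, d = 4, sep = 6, seed = 9)
  curve <- dbi_sweep(b$X, 2:10, seed = 10)
  expect_equal(nrow(curve), 9)
  expect_equal(curve$K[which.min(curve$dbi)], 8L)
})

test_that("an arbitrary split of one blob scores worse than the true partition", {
  b <- make_blobs(30, 2, d = 2, sep = 10, seed = 11)
  true_dbi <- dbi(b$X, b$y)$value
  bad <- as.integer(b$y)
  bad[b$y == 1] <- rep(1:2, length.out = sum(b$y == 1))  # split blob 1
  bad[b$y == 2] <- 1                                     # merge rest
  expect_gt(dbi(b$X, bad)$value, true_dbi)
})

test_that("lower DBI accompanies higher generator separation", {
  vals <- vapply(c(0.3, 0.8, 1.5), function(sep) {
    cfg <- synth_config(n_trials_per_class = 5, n_channels = 2,
                        separation = sep, seed = 55)
    fs <- extract_feature_set(generate_dataset(cfg),
                              feature_config(features = c("wamp", "ewt")))
    Z <- scale(do.call(cbind, fs$sets))
    dbi(Z, fs$labels)$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})
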