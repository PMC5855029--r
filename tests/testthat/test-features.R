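test_that("Wilson amplitude counts threshold crossings", {
  expect_equal(wamp(c(0, 2, 0, 2, 0), 1), 4)
  expect_equal(wamp(stats::rnorm(100), Inf), 0)
  expect_equal(wamp(rep(3, 50), 0), 0)
  expect_error(wamp(1, 0.5), "length >= 2")
  expect_error(wamp(1:10, -1), ">= 0")
})

test_that("fuzzy entropy separates noise from a pure tone and is scale-free", {
  expect_equal(fuzzy_entropy(rep(1, 100)), 0)
  tt <- seq(0, 4 * pi, length.out = 400)
  wins <- sapply(1:10, function(s) {
    set.seed(s)
    fuzzy_entropy(stats::rnorm(400)) > fuzzy_entropy(sin(tt))
  })
  expect_true(all(wins))
  set.seed(3)
  x <- stats::rnorm(300)
  expect_equal(fuzzy_entropy(x), fuzzy_entropy(5 * x - 2),
               tolerance = 1e-8)
  expect_error(fuzzy_entropy(x, r = 0), "positive")
})

test_that("permutation entropy respects its analytic bounds", {
  expect_equal(permutation_entropy(1:100), 0)
  set.seed(4)
  pe <- permutation_entropy(stats::runif(1e5), order = 3)
  expect_lt(abs(pe - log(6)), 0.05)
  expect_lte(pe, log(6))
  expect_error(permutation_entropy(1:10, order = 1), ">= 2")
  expect_error(permutation_entropy(1:3, order = 5), "too short")
})

test_that("cumulant AR estimation recovers planted AR(4) coefficients", {
  a_true <- c(0.55, -0.25, 0.1, -0.05)
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    x <- as.numeric(stats::filter(stats::rexp(1e4) - 1, a_true,
                                  method = "recursive"))
    max(abs(arcu(x) - a_true))
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("cumulant AR estimation on structure-free skewed noise is null", {
  vals <- sapply(1:5, function(s) {
    set.seed(100 + s)
    max(abs(arcu(stats::rexp(1e4) - 1)))
  })
  expect_lt(stats::median(vals), 0.1)
  expect_length(arcu(stats::rexp(500) - 1), 4)
  expect_error(arcu(rep(1, 1000)), "zero-variance")
})

test_that("wavelet-band energies obey Parseval and locate a low tone", {
  expect_equal(ewt(rep(0, 160)), rep(0, 5))
  set.seed(8)
  x <- stats::rnorm(1600)
  expect_equal(sum(ewt(x)), sum(x^2), tolerance = 1e-6 * sum(x^2))
  s <- sin(2 * pi * 2 * (1:2000) / 1000)     # 2 Hz at fs 1000
  expect_equal(which.max(ewt(s)), 5)          # approximation band
  expect_error(ewt(stats::rnorm(100)), "multiple of 2\\^levels")
})

test_that("per-trial extraction is pure and dimensioned like the feature table", {
  cfg <- synth_config(n_trials_per_class = 2, seed = 19)
  tr <- generate_trial("s-a", cfg, 1)
  m1 <- extract_features(tr)
  m2 <- extract_features(tr)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(4, 12))
  expect_equal(colnames(m1),
               c("WAMP", "FE", "PE", paste0("ARCU", 1:4),
                 paste0("EWT", 1:5)))
  expect_true(all(is.finite(m1)))
})

test_that("dataset-level extraction aligns rows with trials and labels", {
  cfg <- synth_config(n_trials_per_class = 2, n_channels = 3, seed = 23)
  ds <- generate_dataset(cfg)
  fs <- extract_feature_set(ds, feature_config(features = c("wamp", "pe")))
  expect_length(fs$sets, 3)
  expect_equal(nrow(fs$sets$ch1), 16)
  expect_equal(length(fs$labels), 16)
  expect_equal(ncol(fs$sets$ch2), 2)
})
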