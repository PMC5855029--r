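test_that("the cosine rate schedule hits its analytic anchors", {
  expect_identical(rate_schedule(0, 30), 1)
  expect_identical(rate_schedule(30, 30), 0)
  expect_equal(rate_schedule(15, 30), sqrt(2) / 2, tolerance = 1e-14)
  sched <- vapply(0:20, rate_schedule, numeric(1), gen_max = 20)
  expect_true(all(diff(sched) < 0))
  expect_error(rate_schedule(31, 30), "gen must be")
  expect_error(rate_schedule(1, 0), "gen_max")
})

test_that("Fisher fitness measures between/within class separation", {
  set.seed(21)
  # shift-free construction: identical class means give zero criterion
  y <- rep(1:4, each = 100)
  Z0 <- cbind(rep(c(-1, 1), 200))
  expect_lt(fisher_fitness(Z0, y), 1e-6)
  expect_lt(fisher_fitness(cbind(stats::rnorm(400)), y), 0.1)
  # two classes at +/-10 with unit variance: ratio approximately 100
  y2 <- rep(1:2, each = 500)
  Z2 <- cbind(ifelse(y2 == 1, -10, 10) + stats::rnorm(1000))
  expect_equal(fisher_fitness(Z2, y2), 100, tolerance = 10)
  expect_error(fisher_fitness(Z2, rep(1, 1000)), ">= 2 classes")
})

test_that("a pure-noise column inflates the finite-sample criterion only slightly", {
  incs <- sapply(1:10, function(s) {
    set.seed(30 + s)
    y <- rep(1:8, each = 100)
    Z <- cbind(stats::rnorm(8, sd = 2)[y] + stats::rnorm(800))
    fisher_fitness(cbind(Z, stats::rnorm(800)), y) - fisher_fitness(Z, y)
  })
  expect_true(all(incs < 0.05))
})

test_that("the GA recovers planted informative columns and is reproducible", {
  inst <- make_planted_ga(seed = 3)
  cfg <- ga_config(seed = 5)
  g1 <- run_ga(inst$Z, inst$y, cfg)
  g2 <- run_ga(inst$Z, inst$y, cfg)
  expect_identical(g1, g2)
  expect_gte(sum(which(g1$best_mask) %in% inst$informative), 3)
  expect_true(all(diff(g1$fitness_trace) >= -1e-12))
  expect_equal(g1$selected_dimension, sum(g1$best_mask))
  ex <- exhaustive_fisher_best(inst$Z, inst$y)
  expect_gte(g1$best_fitness, 0.99 * ex$fitness)
})

test_that("GA boundary cases and input validation", {
  inst <- make_planted_ga(seed = 4, n_per = 10)
  g <- run_ga(inst$Z, inst$y, ga_config(population_size = 2, gen_max = 1,
                                        seed = 1))
  expect_true(any(g$best_mask))
  expect_lte(g$selected_dimension, ncol(inst$Z))
  expect_error(run_ga(inst$Z, rep(1, nrow(inst$Z)), ga_config()),
               "degenerate")
  expect_error(run_ga(inst$Z[, 1, drop = FALSE], inst$y, ga_config()),
               ">= 2 columns")
})
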