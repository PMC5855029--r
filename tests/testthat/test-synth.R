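light_features <- feature_config(features = c("wamp", "pe", "ewt"))

test_that("trial generation is seed-deterministic and well-formed", {
  cfg <- synth_config(n_trials_per_class = 2, seed = 11)
  tr1 <- generate_trial("w", cfg, 3)
  tr2 <- generate_trial("w", cfg, 3)
  expect_identical(tr1$samples, tr2$samples)
  expect_equal(dim(tr1$samples), c(4, 2000))
  expect_true(all(is.finite(tr1$samples)))
  expect_error(generate_trial("jump", cfg), "unknown activity class")
})

test_that("dataset is balanced, counted, and manifest-aligned", {
  cfg <- synth_config(n_trials_per_class = 3, n_channels = 2, seed = 5)
  ds <- generate_dataset(cfg)
  expect_length(ds$trials, 24)
  expect_equal(nrow(ds$manifest), 24)
  expect_true(all(table(ds$manifest$label) == 3))
  expect_identical(vapply(ds$trials, `[[`, character(1), "label"),
                   ds$manifest$label)
  expect_error(synth_config(n_trials_per_class = 0), "must be >= 1")
})

test_that("dataset round-trips through CSV files", {
  cfg <- synth_config(n_trials_per_class = 1, n_channels = 2, seed = 9,
                      duration = 0.5)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$manifest$label, ds$manifest$label)
  expect_equal(ds2$trials[[3]]$samples, ds$trials[[3]]$samples,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("signals are band-limited to the 20-450 Hz sensor band", {
  cfg <- synth_config(n_trials_per_class = 1, seed = 21)
  for (cls in c("w", "fall", "st-sq")) {
    x <- generate_trial(cls, cfg, 1)$samples[1, ]
    P <- Mod(stats::fft(x))^2
    fr <- (seq_along(x) - 1) * cfg$fs / length(x)
    half <- fr <= cfg$fs / 2
    frac_oob <- sum(P[half][fr[half] < 10 | fr[half] > 490]) /
      sum(P[half])
    expect_lt(frac_oob, 0.05)
  }
})

test_that("the fall class is burstier than walking", {
  cfg <- synth_config(n_trials_per_class = 20, n_channels = 1, seed = 31)
  burst_ratio <- function(x) {
    w <- split(x, rep(seq_len(20), each = length(x) / 20))
    r <- vapply(w, function(v) sqrt(mean(v^2)), numeric(1))
    max(r) / stats::median(r)
  }
  ratios <- sapply(1:20, function(ti) c(
    fall = burst_ratio(generate_trial("fall", cfg, ti)$samples[1, ]),
    w = burst_ratio(generate_trial("w", cfg, ti)$samples[1, ])))
  expect_gt(mean(ratios["fall", ]), mean(ratios["w", ]))
  expect_gt(mean(ratios["fall", ] > ratios["w", ]), 0.8)
})

test_that("class separability of extracted features grows with separation", {
  fisher_of <- function(sep) {
    cfg <- synth_config(n_trials_per_class = 8, n_channels = 2,
                        separation = sep, seed = 77)
    fs <- extract_feature_set(generate_dataset(cfg), light_features)
    Z <- scale(do.call(cbind, fs$sets))
    fisher_fitness(Z, fs$labels)
  }
  vals <- vapply(c(0.25, 1, 2), fisher_of, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("separation 0 removes class structure (permutation test)", {
  cfg <- synth_config(n_trials_per_class = 6, n_channels = 2,
                      separation = 0, seed = 13)
  fs <- extract_feature_set(generate_dataset(cfg), light_features)
  Z <- scale(do.call(cbind, fs$sets))
  obs <- fisher_fitness(Z, fs$labels)
  set.seed(99)
  perm <- replicate(200, fisher_fitness(Z, sample(fs$labels)))
  p <- (1 + sum(perm >= obs)) / (length(perm) + 1)
  expect_gt(p, 0.01)
})
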